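#' Analysis plan for a consortium run
#'
#' Bundles the family-wise testing policy and contrast parameters shared by
#' all pipeline stages: the significance threshold is
#' `alpha_family / n_tests`, a Bonferroni correction for testing the nine
#' analyzed measures (0.05 / 9 = 5.6e-3), applied per contrast family of
#' nine measures rather than across families.
#'
#' @param onset_cutoff Age-of-onset cutoff in years; onset at exactly the
#'   cutoff is early (default 21).
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param n_tests Number of measures in the family (default 9).
#' @param tau2_method Between-site variance estimator for all pooling,
#'   `"REML"` (default) or `"DL"`.
#' @param min_sites Minimum number of sites for a poolable result
#'   (default 2).
#' @return An object of class `analysis_plan` with the derived `threshold`.
#' @examples
#' analysis_plan()$threshold
#' @export
analysis_plan <- function(onset_cutoff = 21, alpha_family = 0.05,
                          n_tests = 9, tau2_method = c("REML", "DL"),
                          min_sites = 2) {
  check_alpha(alpha_family)
  stopifnot(n_tests >= 1, min_sites >= 2)
  structure(
    list(
      onset_cutoff = onset_cutoff, alpha_family = alpha_family,
      n_tests = n_tests, threshold = alpha_family / n_tests,
      tau2_method = match.arg(tau2_method), min_sites = min_sites
    ),
    class = "analysis_plan"
  )
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat(
    "<analysis_plan> alpha ", x$alpha_family, " / ", x$n_tests,
    " measures -> threshold ", format(x$threshold, digits = 3),
    "; onset cutoff ", x$onset_cutoff, " y; tau2 by ", x$tau2_method, "\n",
    sep = ""
  )
  invisible(x)
}

# pool one measure's effects into a result row; NA row when not estimable
pool_roi_row <- function(effects, roi, contrast, plan) {
  if (nrow(effects) < plan$min_sites) {
    return(tibble::tibble(
      roi = roi, contrast = contrast, cohens_d = NA_real_, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, z = NA_real_,
      p_value = NA_real_, q_stat = NA_real_, tau2 = NA_real_,
      i2 = NA_real_, k_sites = nrow(effects),
      n_controls = NA_integer_, n_patients = NA_integer_,
      pct_difference = NA_real_, estimable = FALSE
    ))
  }
  m <- pool_random_effects(effects, tau2_method = plan$tau2_method)
  tibble::tibble(
    roi = roi, contrast = contrast, cohens_d = m$pooled, se = m$se,
    ci_low = m$ci_low, ci_high = m$ci_high, z = m$z, p_value = m$p_value,
    q_stat = m$q_stat, tau2 = m$tau2, i2 = m$i2, k_sites = m$k,
    n_controls = m$n_controls, n_patients = m$n_cases,
    pct_difference = m$pct_difference, estimable = TRUE
  )
}

run_contrast <- function(subjects, plan, contrast, rois = roi_names()) {
  effects <- site_effect_sizes(
    subjects,
    rois = rois, contrast = contrast, onset_cutoff = plan$onset_cutoff
  )
  rows <- purrr::map(rois, function(roi) {
    pool_roi_row(
      effects[effects$roi == roi, , drop = FALSE], roi, contrast, plan
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = !is.na(.data$p_value) &
      .data$p_value < plan$threshold)
  attr(out, "run_log") <- run_log(effects)
  attr(out, "effects") <- effects
  attr(out, "plan") <- plan
  out
}

#' Primary case-control meta-analysis over the nine measures
#'
#' The consortium's primary analysis: for each of the nine measures, fit
#' the covariate-adjusted regression at every site, convert the diagnosis
#' t-statistic to Cohen's d, and pool across sites with the random-effects
#' model. ICV is analyzed without the ICV covariate. Results with
#' `p_value < alpha_family / n_tests` are flagged `significant`; a measure
#' for which fewer than `min_sites` sites pass preconditions is reported
#' with `estimable = FALSE` rather than aborting the run.
#'
#' @param subjects Subject tibble across sites (as from
#'   [simulate_consortium()]`$subjects` or row-bound [read_site_table()]
#'   outputs).
#' @param plan An [analysis_plan()].
#' @param rois Measures to analyze (default all nine).
#' @return Tibble with one row per measure: `roi`, `contrast`, `cohens_d`,
#'   `se`, `ci_low`, `ci_high`, `z`, `p_value`, `q_stat`, `tau2`, `i2`,
#'   `k_sites`, `n_controls`, `n_patients`, `pct_difference`, `estimable`,
#'   `significant`. Per-site effects in `attr(, "effects")`, exclusions in
#'   [run_log()].
#' @examples
#' sim <- simulate_consortium(sim_config(
#'   n_sites = 4, n_cases_total = 80,
#'   n_controls_total = 160, seed = 1
#' ))
#' run_primary(sim$subjects, rois = "hippocampus")
#' @export
run_primary <- function(subjects, plan = analysis_plan(), rois = roi_names()) {
  run_contrast(subjects, plan, "MDD_vs_CTL", rois)
}

#' Stratified and patient-vs-patient meta-analyses
#'
#' Reruns the per-site models with patients restricted to a clinical
#' stratum (first episode, recurrent, early onset `<= cutoff`, late onset),
#' reusing all controls for each patient stratum, and pools as in
#' [run_primary()]. The patient-vs-patient strata (`"recurrent_vs_first"`,
#' `"early_vs_late"`) are direct two-patient-group regressions pooled via
#' [compare_groups()]. `stratum = "all_MDD_vs_CTL"` reproduces
#' [run_primary()] exactly.
#'
#' @inheritParams run_primary
#' @param stratum One of `"all_MDD_vs_CTL"`, `"first_vs_CTL"`,
#'   `"recurrent_vs_CTL"`, `"recurrent_vs_first"`, `"early_onset_vs_CTL"`,
#'   `"late_onset_vs_CTL"`, `"early_vs_late"`, `"dx_by_sex"`.
#' @return As [run_primary()].
#' @export
run_stratified <- function(subjects, plan = analysis_plan(),
                           stratum = c(
                             "all_MDD_vs_CTL", "first_vs_CTL",
                             "recurrent_vs_CTL", "recurrent_vs_first",
                             "early_onset_vs_CTL", "late_onset_vs_CTL",
                             "early_vs_late", "dx_by_sex"
                           ),
                           rois = roi_names()) {
  stratum <- match.arg(stratum)
  contrast <- if (stratum == "all_MDD_vs_CTL") "MDD_vs_CTL" else stratum
  run_contrast(subjects, plan, contrast, rois)
}

#' Severity meta-analysis (partial correlations)
#'
#' For each measure, computes the within-site partial correlation between
#' the chosen severity scale and volume among patients
#' ([severity_model()]) and pools across sites on the correlation scale.
#' Scales are analyzed separately and never mixed, since pooling different
#' severity instruments in one meta-analysis risks bias; sites not
#' administering the scale are excluded with a run-log entry.
#'
#' @inheritParams run_primary
#' @param scale `"hdrs17"` or `"bdi_ii"`.
#' @param r_scale Pooling scale, `"raw"` (default) or `"fisher_z"`; see
#'   [pool_random_effects()].
#' @return Tibble with one row per measure: `roi`, `contrast`, `pearson_r`,
#'   `se`, `ci_low`, `ci_high`, `z`, `p_value`, `q_stat`, `tau2`, `i2`,
#'   `k_sites`, `n_patients`, `estimable`, `significant`.
#' @export
run_severity <- function(subjects, plan = analysis_plan(),
                         scale = c("hdrs17", "bdi_ii"),
                         r_scale = c("raw", "fisher_z"),
                         rois = roi_names()) {
  scale <- match.arg(scale)
  r_scale <- match.arg(r_scale)
  contrast <- paste0("severity_", scale)
  per_site <- split(subjects, subjects$site_id)
  log <- list()
  rows <- list()
  for (site in per_site) {
    for (roi in rois) {
      res <- tryCatch(
        severity_model(site, roi, scale),
        sitemeta_contrast_error = function(e) e,
        sitemeta_singularity_error = function(e) e
      )
      if (inherits(res, "condition")) {
        log[[length(log) + 1]] <- tibble::tibble(
          site_id = site_id_of(site), roi = roi, contrast = contrast,
          reason = res$reason %||% conditionMessage(res)
        )
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  effects <- if (length(rows) > 0) dplyr::bind_rows(rows) else NULL
  out <- dplyr::bind_rows(purrr::map(rois, function(roi) {
    es <- if (is.null(effects)) NULL else
      effects[effects$roi == roi, , drop = FALSE]
    if (is.null(es) || nrow(es) < plan$min_sites) {
      return(tibble::tibble(
        roi = roi, contrast = contrast, pearson_r = NA_real_, se = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, z = NA_real_,
        p_value = NA_real_, q_stat = NA_real_, tau2 = NA_real_,
        i2 = NA_real_, k_sites = if (is.null(es)) 0L else nrow(es),
        n_patients = NA_integer_, estimable = FALSE
      ))
    }
    m <- pool_random_effects(es,
      tau2_method = plan$tau2_method, r_scale = r_scale
    )
    tibble::tibble(
      roi = roi, contrast = contrast, pearson_r = m$pooled, se = m$se,
      ci_low = m$ci_low, ci_high = m$ci_high, z = m$z, p_value = m$p_value,
      q_stat = m$q_stat, tau2 = m$tau2, i2 = m$i2, k_sites = m$k,
      n_patients = m$n, estimable = TRUE
    )
  })) |>
    dplyr::mutate(significant = !is.na(.data$p_value) &
      .data$p_value < plan$threshold)
  attr(out, "run_log") <- if (length(log) > 0) dplyr::bind_rows(log) else
    empty_run_log()
  attr(out, "effects") <- effects
  attr(out, "plan") <- plan
  out
}

#' Site-level moderator battery via meta-regression
#'
#' For each (moderator, measure) pair, enters the moderator alone as a
#' fixed-effect predictor of the per-site effect sizes in a mixed-effects
#' meta-regression ([meta_regress()]). Categorical moderators
#' (`software_version`) are encoded as a single numeric code
#' (`as.integer(factor(x))`); sites missing a moderator value are dropped
#' for that moderator with a run-log entry.
#'
#' @inheritParams run_primary
#' @param site_info Site metadata tibble (one row per site: `site_id`,
#'   moderator columns), as from [read_site_metadata()] or
#'   [simulate_consortium()]`$sites`.
#' @param moderators Character vector of moderator column names; defaults
#'   to mean age, field strength, software version and the medication /
#'   clinical-composition percentages.
#' @param contrast Contrast whose per-site effects are moderated (default
#'   primary).
#' @param effects Optional precomputed per-site effects (as stored in
#'   `attr(run_primary(...), "effects")`); computed if `NULL`.
#' @return Tibble with one row per moderator x measure: `moderator`, `roi`,
#'   `beta`, `se_beta`, `p_value`, `residual_tau2`, `k_sites`, `estimable`.
#' @export
run_moderators <- function(subjects, site_info, plan = analysis_plan(),
                           moderators = c(
                             "mean_age", "field_strength",
                             "software_version", "pct_acute",
                             "pct_comorbid_anxiety", "pct_antidepressant",
                             "pct_antipsychotic"
                           ),
                           contrast = "MDD_vs_CTL", rois = roi_names(),
                           effects = NULL) {
  stopifnot("site_id" %in% names(site_info))
  if (is.null(effects)) {
    effects <- site_effect_sizes(subjects,
      rois = rois, contrast = contrast,
      onset_cutoff = plan$onset_cutoff
    )
  }
  log <- list()
  rows <- list()
  for (mod in moderators) {
    if (!mod %in% names(site_info)) {
      abort(paste0("site_info lacks moderator column ", mod),
        class = "sitemeta_schema_error"
      )
    }
    vals <- site_info[[mod]]
    if (is.character(vals) || is.factor(vals)) {
      vals <- as.integer(factor(vals))
    }
    lut <- setNames(as.numeric(vals), site_info$site_id)
    for (roi in rois) {
      es <- effects[effects$roi == roi, , drop = FALSE]
      x <- unname(lut[es$site_id])
      dropped <- es$site_id[is.na(x)]
      for (sid in dropped) {
        log[[length(log) + 1]] <- tibble::tibble(
          site_id = sid, roi = roi, contrast = contrast,
          reason = paste0("missing_moderator:", mod)
        )
      }
      res <- tryCatch(
        meta_regress(es, x, moderator_name = mod),
        sitemeta_estimability_error = function(e) e,
        sitemeta_collinearity_error = function(e) e,
        sitemeta_pooling_error = function(e) e
      )
      rows[[length(rows) + 1]] <- if (inherits(res, "condition")) {
        tibble::tibble(
          moderator = mod, roi = roi, beta = NA_real_, se_beta = NA_real_,
          p_value = NA_real_, residual_tau2 = NA_real_,
          k_sites = sum(!is.na(x)), estimable = FALSE
        )
      } else {
        tibble::tibble(
          moderator = mod, roi = roi, beta = res$beta,
          se_beta = res$se_beta, p_value = res$p_value,
          residual_tau2 = res$residual_tau2, k_sites = res$k,
          estimable = TRUE
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "run_log") <- if (length(log) > 0) dplyr::bind_rows(log) else
    empty_run_log()
  attr(out, "plan") <- plan
  out
}
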