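#' Per-site covariate-adjusted regression for one measure
#'
#' Fits the prespecified site-level ordinary least-squares model: mean
#' ((left+right)/2) structure volume regressed on an intercept, the group
#' indicator of the requested contrast, age, sex and ICV, plus scanner
#' indicator columns when the site pools two or more scanners (k-1 dummies,
#' reference = lexicographically first `scanner_id`). When the outcome is
#' `"icv"` the ICV covariate is omitted (ICV is corrected for age and sex
#' only). Missing data are handled by listwise deletion per outcome, so the
#' analyzed n varies across measures.
#'
#' @param site Subject tibble for a single site.
#' @param roi One of [roi_names()].
#' @param contrast Contrast label. `"MDD_vs_CTL"` (all patients vs controls,
#'   indicator 0 = control, 1 = patient), `"first_vs_CTL"`,
#'   `"recurrent_vs_CTL"`, `"early_onset_vs_CTL"`, `"late_onset_vs_CTL"`
#'   (the patient stratum vs all controls), or the patient-vs-patient
#'   contrasts `"recurrent_vs_first"` (recurrent = 1) and `"early_vs_late"`
#'   (early onset = 1).
#' @param onset_cutoff Age-of-onset cutoff in years for the onset strata;
#'   onset at exactly the cutoff counts as early (default 21).
#' @return An object of class `site_fit`: the group-indicator coefficient
#'   (mm^3), its `t_stat` and residual `df`, group sizes `n_cases` /
#'   `n_controls` (group 1 / group 0), and covariate-adjusted group means
#'   evaluated at the pooled covariate means of the analyzed sample.
#' @examples
#' site <- make_fixture("tiny_site")
#' fit_site_model(site, "hippocampus")
#' @export
fit_site_model <- function(site, roi, contrast = "MDD_vs_CTL",
                           onset_cutoff = 21) {
  roi <- match.arg(roi, roi_names())
  dat <- contrast_frame(site, roi, contrast, onset_cutoff)
  fit_group_model(dat, roi, contrast,
    site_id = site_id_of(site),
    extra_terms = character(0)
  )
}

site_id_of <- function(site) {
  ids <- unique(site$site_id)
  if (length(ids) == 1) ids else NA_character_
}

# subset the site to a contrast's groups and build the 0/1 indicator
contrast_frame <- function(site, roi, contrast, onset_cutoff) {
  has <- function(col) col %in% names(site)
  need_clinical <- function(col) {
    if (!has(col)) {
      abort_contrast(
        paste0("contrast ", contrast, " requires column ", col),
        reason = "missing_clinical_column"
      )
    }
  }
  grp <- switch(contrast,
    MDD_vs_CTL = site$diagnosis,
    first_vs_CTL = {
      need_clinical("episode_status")
      ifelse(site$diagnosis == 0, 0,
        ifelse(site$episode_status == "first", 1, NA)
      )
    },
    recurrent_vs_CTL = {
      need_clinical("episode_status")
      ifelse(site$diagnosis == 0, 0,
        ifelse(site$episode_status == "recurrent", 1, NA)
      )
    },
    recurrent_vs_first = {
      need_clinical("episode_status")
      ifelse(site$diagnosis == 1 & site$episode_status == "recurrent", 1,
        ifelse(site$diagnosis == 1 & site$episode_status == "first", 0, NA)
      )
    },
    early_onset_vs_CTL = {
      need_clinical("age_of_onset")
      ifelse(site$diagnosis == 0, 0,
        ifelse(site$age_of_onset <= onset_cutoff, 1, NA)
      )
    },
    late_onset_vs_CTL = {
      need_clinical("age_of_onset")
      ifelse(site$diagnosis == 0, 0,
        ifelse(site$age_of_onset > onset_cutoff, 1, NA)
      )
    },
    early_vs_late = {
      need_clinical("age_of_onset")
      ifelse(site$diagnosis == 1 & site$age_of_onset <= onset_cutoff, 1,
        ifelse(site$diagnosis == 1 & site$age_of_onset > onset_cutoff, 0, NA)
      )
    },
    abort_domain(paste0("unknown contrast: ", contrast))
  )
  dat <- data.frame(
    y = site[[roi]] %||%
      abort_domain(paste0("site table lacks measure column ", roi)),
    grp = grp, age = site$age, sex = site$sex
  )
  if (roi != "icv") dat$icv <- site$icv
  if ("scanner_id" %in% names(site)) dat$scanner_id <- site$scanner_id
  dat[complete.cases(dat[setdiff(names(dat), "scanner_id")]), , drop = FALSE]
}

# core OLS fit on a prepared frame with columns y, grp, covariates
fit_group_model <- function(dat, roi, contrast, site_id,
                            extra_terms = character(0)) {
  n1 <- sum(dat$grp == 1)
  n0 <- sum(dat$grp == 0)
  if (n1 < 1 || n0 < 1) {
    abort_contrast(
      paste0(
        "contrast ", contrast, " for ", roi, " has an empty group (",
        n0, " vs ", n1, ")"
      ),
      reason = "empty_group"
    )
  }
  use_scanner <- "scanner_id" %in% names(dat) &&
    length(unique(dat$scanner_id)) >= 2
  rhs <- c("grp", "age", "sex", if ("icv" %in% names(dat)) "icv",
    extra_terms, if (use_scanner) "factor(scanner_id)"
  )
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  mm <- model.matrix(form, data = dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(
      paste0(
        "design matrix is rank deficient; aliased column(s): ",
        paste(aliased, collapse = ", ")
      ),
      class = "sitemeta_singularity_error", reason = "rank_deficient"
    )
  }
  if (nrow(mm) - ncol(mm) < 1) {
    abort_contrast(
      paste0("fewer subjects than coefficients + 1 for ", roi),
      reason = "insufficient_df"
    )
  }
  fit <- lm(form, data = dat)
  ct <- summary(fit)$coefficients
  term <- if (length(extra_terms) > 0) "grp:sex" else "grp"
  # adjusted means: group indicator set to 0/1, all other columns at the
  # pooled (cases + controls) means of the analyzed sample
  xbar <- colMeans(mm)
  b <- coef(fit)
  x0 <- x1 <- xbar
  x0["grp"] <- 0
  x1["grp"] <- 1
  if (term == "grp:sex") {
    x0["grp:sex"] <- 0
    x1["grp:sex"] <- 1 * xbar["sex"]
  }
  structure(
    list(
      site_id = site_id, roi = roi, contrast = contrast, term = term,
      coefficient = unname(b[term]),
      t_stat = unname(ct[term, "t value"]),
      df_residual = fit$df.residual,
      n_cases = n1, n_controls = n0, n_coef = length(b),
      adjusted_mean_cases = unname(sum(x1 * b)),
      adjusted_mean_controls = unname(sum(x0 * b))
    ),
    class = "site_fit"
  )
}

#' @export
print.site_fit <- function(x, ...) {
  cat(
    "<site_fit> ", x$site_id, " | ", x$roi, " | ", x$contrast, "\n",
    "  term ", x$term, ": coef = ", format(x$coefficient, digits = 4),
    ", t = ", format(x$t_stat, digits = 4),
    ", df = ", x$df_residual,
    ", n = ", x$n_cases, "/", x$n_controls, "\n",
    sep = ""
  )
  invisible(x)
}

#' Cohen's d from a regression t-statistic
#'
#' Converts the group-indicator t-statistic of a covariate-adjusted
#' regression into a standardized mean difference:
#' \deqn{d = t\,(n_1+n_2) / (\sqrt{n_1 n_2}\,\sqrt{df}),}
#' with sampling variance
#' \deqn{v = (n_1+n_2)/(n_1 n_2) + d^2 / (2 (n_1+n_2)).}
#' Positive d means larger volume in the group coded 1 (patients). No
#' small-sample correction is applied by default; set
#' `hedges_correction = TRUE` for Hedges' g (factor `1 - 3/(4 df - 1)`).
#'
#' @param t t-statistic of the group indicator.
#' @param n1,n2 Group sizes (cases, controls), each `>= 1`.
#' @param df Residual degrees of freedom, `>= 1`.
#' @param hedges_correction Apply the small-sample correction (default
#'   `FALSE`).
#' @return One-row tibble: `metric`, `value`, `variance`, `n_cases`,
#'   `n_controls`, `t_stat`, `df`.
#' @examples
#' cohens_d_from_t(2, 50, 50, 96)
#' @export
cohens_d_from_t <- function(t, n1, n2, df, hedges_correction = FALSE) {
  dv <- d_from_t_scalar(t, n1, n2, df, hedges_correction)
  tibble::tibble(
    metric = "cohens_d", value = dv$d, variance = dv$v,
    n_cases = n1, n_controls = n2, t_stat = t, df = df
  )
}

d_from_t_scalar <- function(t, n1, n2, df, hedges_correction = FALSE) {
  if (df < 1) abort_domain("df must be >= 1")
  if (n1 < 1 || n2 < 1) abort_domain("group sizes must be >= 1")
  d <- t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
  j <- if (hedges_correction) 1 - 3 / (4 * df - 1) else 1
  d <- d * j
  v <- ((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))) * j^2
  list(d = d, v = v)
}

#' Partial correlation from a regression t-statistic
#'
#' Converts the t-statistic of a continuous predictor (after removing
#' nuisance variables) into the partial correlation
#' \eqn{r = t / \sqrt{t^2 + df}}, with sampling variance
#' \eqn{(1 - r^2)^2 / (n - m - 1)} where `m` is the number of partialled
#' nuisance covariates. `n` and `m` are retained so the pooling step can
#' alternatively work on the Fisher-z scale (variance `1/(n - m - 3)`).
#'
#' @param t t-statistic of the predictor of interest.
#' @param df Residual degrees of freedom, `>= 1`.
#' @param n Number of subjects in the fit (defaults to `df + m + 2`,
#'   i.e. intercept + predictor + m nuisance terms).
#' @param n_partialled Number of partialled nuisance covariates `m`
#'   (default 3: age, sex, ICV).
#' @return One-row tibble: `metric`, `value`, `variance`, `n`,
#'   `n_partialled`, `t_stat`, `df`.
#' @examples
#' partial_r_from_t(3, 9)
#' @export
partial_r_from_t <- function(t, df, n = df + n_partialled + 2,
                             n_partialled = 3) {
  if (df < 1) abort_domain("df must be >= 1")
  r <- t / sqrt(t^2 + df)
  denom <- n - n_partialled - 1
  if (denom <= 0) abort_domain("n - n_partialled - 1 must be positive")
  tibble::tibble(
    metric = "pearson_r", value = r, variance = (1 - r^2)^2 / denom,
    n = n, n_partialled = n_partialled, t_stat = t, df = df
  )
}

#' Covariate-adjusted percent volume difference
#'
#' `100 * (adjusted mean cases - adjusted mean controls) / adjusted mean
#' controls`, with the adjusted means evaluated at the pooled covariate
#' means of the site sample (least-squares means).
#'
#' @param reg A `site_fit` from [fit_site_model()].
#' @return Percent difference (scalar).
#' @examples
#' percent_difference(fit_site_model(make_fixture("tiny_site"), "hippocampus"))
#' @export
percent_difference <- function(reg) {
  stopifnot(inherits(reg, "site_fit"))
  if (abs(reg$adjusted_mean_controls) < .Machine$double.eps) {
    abort_domain("adjusted control mean is zero; percent difference undefined")
  }
  100 * (reg$adjusted_mean_cases - reg$adjusted_mean_controls) /
    reg$adjusted_mean_controls
}

#' Diagnosis-by-sex interaction model
#'
#' Adds the diagnosis x sex product term to the standard site model (main
#' effects retained) and returns the interaction term's coefficient, t and
#' df for conversion to Cohen's d. Requires both sexes and both diagnostic
#' groups at the site; the sex coding is symmetric (swapping 0/1 flips the
#' coefficient's sign, |t| unchanged).
#'
#' @inheritParams fit_site_model
#' @return A `site_fit` whose `term` is `grp:sex`.
#' @export
fit_interaction_model <- function(site, roi) {
  roi <- match.arg(roi, roi_names())
  dat <- contrast_frame(site, roi, "MDD_vs_CTL", onset_cutoff = 21)
  if (length(unique(dat$sex)) < 2) {
    abort_contrast(
      paste0("single-sex site: diagnosis-by-sex interaction not estimable"),
      reason = "single_sex"
    )
  }
  fit_group_model(dat, roi, "dx_by_sex",
    site_id = site_id_of(site), extra_terms = "grp:sex"
  )
}

#' Severity-volume association among patients
#'
#' Regresses structure volume on a continuous symptom-severity score plus
#' the nuisance covariates age, sex and ICV (and scanner indicators when
#' present), among patients only, and converts the severity t-statistic to a
#' partial correlation via [partial_r_from_t()]. Controls are excluded;
#' scales are never mixed.
#'
#' @inheritParams fit_site_model
#' @param scale `"hdrs17"` (clinician-rated, 0-52) or `"bdi_ii"`
#'   (self-rated, 0-63).
#' @return One-row effect tibble as from [partial_r_from_t()], plus
#'   `site_id`, `roi`, `contrast`.
#' @export
severity_model <- function(site, roi, scale = c("hdrs17", "bdi_ii")) {
  roi <- match.arg(roi, roi_names())
  scale <- match.arg(scale)
  if (!scale %in% names(site)) {
    abort_contrast(paste0("site table lacks severity column ", scale),
      reason = "missing_scale"
    )
  }
  dat <- data.frame(
    y = site[[roi]], sev = site[[scale]], age = site$age, sex = site$sex,
    dx = site$diagnosis
  )
  if (roi != "icv") dat$icv <- site$icv
  if ("scanner_id" %in% names(site)) dat$scanner_id <- site$scanner_id
  dat <- dat[dat$dx == 1, setdiff(names(dat), "dx"), drop = FALSE]
  dat <- dat[complete.cases(dat[setdiff(names(dat), "scanner_id")]), ,
    drop = FALSE
  ]
  use_scanner <- "scanner_id" %in% names(dat) &&
    length(unique(dat$scanner_id)) >= 2
  rhs <- c("sev", "age", "sex", if ("icv" %in% names(dat)) "icv",
    if (use_scanner) "factor(scanner_id)"
  )
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  p <- qr(model.matrix(form, data = dat))$rank
  if (nrow(dat) < p + 2) {
    abort_contrast(
      paste0(
        "too few patients with non-missing ", scale, " for ", roi, " (",
        nrow(dat), ")"
      ),
      reason = "insufficient_patients"
    )
  }
  fit <- lm(form, data = dat)
  ct <- summary(fit)$coefficients
  n_partialled <- length(coef(fit)) - 2 # all terms except intercept + severity
  out <- partial_r_from_t(
    t = unname(ct["sev", "t value"]), df = fit$df.residual,
    n = nrow(dat), n_partialled = n_partialled
  )
  tibble::tibble(
    site_id = site_id_of(site), roi = roi,
    contrast = paste0("severity_", scale), out
  )
}

#' Per-site effect sizes across sites and measures
#'
#' The site-level workhorse: for every site and requested measure, fits the
#' contrast's covariate-adjusted regression ([fit_site_model()] or
#' [fit_interaction_model()]) and converts the group-indicator t-statistic
#' to Cohen's d ([cohens_d_from_t()]). Sites failing a contrast's
#' preconditions (empty group, rank-deficient design, too few residual df)
#' are excluded from that measure with a run-log entry, never silently.
#'
#' @param subjects Subject tibble for one or more sites (column `site_id`).
#' @param rois Measures to analyze (default all nine).
#' @param contrast Contrast label; see [fit_site_model()], plus
#'   `"dx_by_sex"` for the diagnosis-by-sex interaction.
#' @param onset_cutoff Age-of-onset cutoff in years (default 21).
#' @param hedges_correction Passed to [cohens_d_from_t()].
#' @return Tibble with one row per site x measure: `site_id`, `roi`,
#'   `contrast`, `metric`, `value`, `variance`, `n_cases`, `n_controls`,
#'   `t_stat`, `df`, `pct_difference`; exclusions in [run_log()].
#' @examples
#' sim <- simulate_consortium(sim_config(
#'   n_sites = 3, n_cases_total = 60,
#'   n_controls_total = 120, seed = 7
#' ))
#' site_effect_sizes(sim$subjects, rois = "hippocampus")
#' @export
site_effect_sizes <- function(subjects, rois = roi_names(),
                              contrast = "MDD_vs_CTL", onset_cutoff = 21,
                              hedges_correction = FALSE) {
  rois <- match.arg(rois, roi_names(), several.ok = TRUE)
  per_site <- split(subjects, subjects$site_id)
  # plain accumulators: this loop is the pipeline's hot path
  acc <- list(
    site_id = character(), roi = character(), value = double(),
    variance = double(), n_cases = integer(), n_controls = integer(),
    t_stat = double(), df = double(), pct_difference = double()
  )
  log_site <- character()
  log_roi <- character()
  log_reason <- character()
  for (site in per_site) {
    sid <- site_id_of(site)
    for (roi in rois) {
      res <- tryCatch(
        {
          fit <- if (contrast == "dx_by_sex") {
            fit_interaction_model(site, roi)
          } else {
            fit_site_model(site, roi, contrast, onset_cutoff)
          }
          dv <- d_from_t_scalar(
            fit$t_stat, fit$n_cases, fit$n_controls, fit$df_residual,
            hedges_correction = hedges_correction
          )
          list(fit = fit, dv = dv)
        },
        sitemeta_contrast_error = function(e) e,
        sitemeta_singularity_error = function(e) e,
        sitemeta_domain_error = function(e) e
      )
      if (inherits(res, "condition")) {
        log_site <- c(log_site, sid)
        log_roi <- c(log_roi, roi)
        log_reason <- c(log_reason, res$reason %||% conditionMessage(res))
      } else {
        fit <- res$fit
        i <- length(acc$site_id) + 1L
        acc$site_id[i] <- sid
        acc$roi[i] <- roi
        acc$value[i] <- res$dv$d
        acc$variance[i] <- res$dv$v
        acc$n_cases[i] <- fit$n_cases
        acc$n_controls[i] <- fit$n_controls
        acc$t_stat[i] <- fit$t_stat
        acc$df[i] <- fit$df_residual
        acc$pct_difference[i] <- if (contrast == "dx_by_sex") NA_real_ else
          percent_difference(fit)
      }
    }
  }
  out <- tibble::tibble(
    site_id = acc$site_id, roi = acc$roi, contrast = rep_len(
      contrast,
      length(acc$site_id)
    ),
    metric = rep_len("cohens_d", length(acc$site_id)),
    value = acc$value, variance = acc$variance, n_cases = acc$n_cases,
    n_controls = acc$n_controls, t_stat = acc$t_stat, df = acc$df,
    pct_difference = acc$pct_difference
  )
  attr(out, "run_log") <- tibble::tibble(
    site_id = log_site, roi = log_roi,
    contrast = rep_len(contrast, length(log_site)), reason = log_reason
  )
  out
}
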