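#' Configuration for the synthetic consortium generator
#'
#' Defaults emulate the consortium the pipeline is designed for: 15 sites
#' totaling 1728 patients and 7199 controls, a true standardized hippocampal
#' case-control deficit of -0.14 (all other measures null), about 65.7% of
#' patients with recurrent episodes, about 35.2% with early onset (first
#' episode at age <= 21) of whom 57% are recurrent, and site-level
#' heterogeneity in both baseline volumes and the true effect. True effects
#' are injected on the standardized (residual-SD) scale, so `delta` is
#' directly comparable to the Cohen's d the pipeline recovers.
#'
#' @param n_sites Number of sites (default 15).
#' @param n_cases_total,n_controls_total Consortium totals (defaults 1728 /
#'   7199); per-site sizes are drawn from seeded lognormal weights.
#' @param delta Named numeric: true standardized case-control effect per
#'   measure (positive = larger in patients). Unnamed measures are 0;
#'   default `c(hippocampus = -0.14)`.
#' @param delta_recurrent Optional named numeric: additional standardized
#'   effect applied only to recurrent-episode patients (so
#'   `delta = c(hippocampus = 0)`, `delta_recurrent = c(hippocampus = -0.17)`
#'   yields a recurrent-only deficit).
#' @param tau Between-site SD of the true standardized effect (default
#'   0.05).
#' @param roi_mean,roi_sd Named numeric, mm^3: population mean and residual
#'   SD per measure (mean of left and right); defaults are typical adult
#'   values.
#' @param beta_age Named numeric, mm^3 per year of age.
#' @param beta_sex Named numeric, mm^3 shift for sex = 1 (male).
#' @param beta_icv Named numeric, mm^3 per mm^3 of ICV (dimensionless).
#' @param site_intercept_sd_frac Site random intercept SD as a fraction of
#'   the measure mean (default 0.03).
#' @param pct_recurrent Percent of patients with recurrent episodes
#'   (default 65.7).
#' @param pct_early_onset Percent of patients with onset <= 21 (default
#'   35.2).
#' @param pct_early_recurrent Percent of early-onset patients who are
#'   recurrent (default 57); recurrence among late-onset patients is set so
#'   the overall `pct_recurrent` holds.
#' @param severity_assoc Optional `list(roi =, r =)` injecting a partial
#'   correlation `r` between both severity scales and the named measure's
#'   residual; by default severity is generated independent of volume.
#' @param moderator_effect Optional `list(roi =, moderator =, beta =)`
#'   adding `beta * (x_s - mean(x_s))` to the named measure's site effect,
#'   where `x_s` is the site's value of the named moderator (e.g.
#'   `pct_antipsychotic`) — used to exercise meta-regression recovery.
#' @param missing_roi_rate Per-cell missingness rate for the eight
#'   structure volumes (default 0.02), so per-measure analyzed n varies;
#'   ICV is complete.
#' @param single_sex_sites Integer indices of sites generated with one sex
#'   only (edge case; default none).
#' @param prob_scale Probability a site administers each severity scale
#'   (default 0.65, drawn independently per scale).
#' @param seed Integer seed; the seed fully determines the output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 15,
                       n_cases_total = 1728,
                       n_controls_total = 7199,
                       delta = c(hippocampus = -0.14),
                       delta_recurrent = NULL,
                       tau = 0.05,
                       roi_mean = NULL, roi_sd = NULL,
                       beta_age = NULL, beta_sex = NULL, beta_icv = NULL,
                       site_intercept_sd_frac = 0.03,
                       pct_recurrent = 65.7,
                       pct_early_onset = 35.2,
                       pct_early_recurrent = 57,
                       severity_assoc = NULL,
                       moderator_effect = NULL,
                       missing_roi_rate = 0.02,
                       single_sex_sites = integer(0),
                       prob_scale = 0.65,
                       seed = 1L) {
  rois <- roi_names()
  vols <- roi_names(include_icv = FALSE)
  fill <- function(x, defaults) {
    out <- defaults
    if (!is.null(x)) {
      bad <- setdiff(names(x), rois)
      if (length(bad) > 0) {
        abort(paste0("unknown measure(s): ", paste(bad, collapse = ", ")),
          class = "sitemeta_config_error"
        )
      }
      out[names(x)] <- x
    }
    out
  }
  cfg <- list(
    n_sites = n_sites,
    n_cases_total = n_cases_total, n_controls_total = n_controls_total,
    delta = fill(delta, setNames(numeric(9), rois)),
    delta_recurrent = if (is.null(delta_recurrent)) NULL else
      fill(delta_recurrent, setNames(numeric(9), rois)),
    tau = tau,
    roi_mean = fill(roi_mean, c(
      lateral_ventricles = 7700, thalamus = 7300, caudate = 3500,
      putamen = 5000, pallidum = 1800, hippocampus = 4100, amygdala = 1600,
      accumbens = 600, icv = 1.5e6
    )),
    roi_sd = fill(roi_sd, c(
      lateral_ventricles = 3500, thalamus = 700, caudate = 400,
      putamen = 550, pallidum = 220, hippocampus = 400, amygdala = 200,
      accumbens = 100, icv = 1.3e5
    )),
    beta_age = fill(beta_age, c(
      lateral_ventricles = 60, thalamus = -12, caudate = -5, putamen = -8,
      pallidum = -3, hippocampus = -6, amygdala = -2, accumbens = -1.5,
      icv = 0
    )),
    beta_sex = fill(beta_sex, setNames(
      c(400, 250, 120, 180, 70, 120, 60, 25, 0), rois
    )),
    beta_icv = fill(beta_icv, setNames(
      c(
        7700 / 1.5e6, 7300 / 1.5e6, 3500 / 1.5e6, 5000 / 1.5e6,
        1800 / 1.5e6, 4100 / 1.5e6, 1600 / 1.5e6, 600 / 1.5e6, 0
      ),
      rois
    )),
    site_intercept_sd_frac = site_intercept_sd_frac,
    pct_recurrent = pct_recurrent,
    pct_early_onset = pct_early_onset,
    pct_early_recurrent = pct_early_recurrent,
    severity_assoc = severity_assoc,
    moderator_effect = moderator_effect,
    missing_roi_rate = missing_roi_rate,
    single_sex_sites = as.integer(single_sex_sites),
    prob_scale = prob_scale,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) abort(msg, class = "sitemeta_config_error")
  if (cfg$n_sites < 1) bad("n_sites must be >= 1")
  if (cfg$n_cases_total < 2 * cfg$n_sites ||
    cfg$n_controls_total < 2 * cfg$n_sites) {
    bad("need at least 2 cases and 2 controls per site on average")
  }
  if (cfg$tau < 0) bad("tau must be >= 0")
  if (any(cfg$roi_sd < 0) || cfg$site_intercept_sd_frac < 0) {
    bad("all SDs must be >= 0")
  }
  pcts <- c(cfg$pct_recurrent, cfg$pct_early_onset, cfg$pct_early_recurrent)
  if (any(pcts < 0 | pcts > 100)) bad("percentages must be in [0, 100]")
  if (cfg$missing_roi_rate < 0 || cfg$missing_roi_rate > 1) {
    bad("missing_roi_rate must be in [0, 1]")
  }
  if (cfg$prob_scale < 0 || cfg$prob_scale > 1) {
    bad("prob_scale must be in [0, 1]")
  }
  if (!is.null(cfg$severity_assoc) &&
    (abs(cfg$severity_assoc$r) >= 1 ||
      !cfg$severity_assoc$roi %in% roi_names())) {
    bad("severity_assoc must give a measure name and |r| < 1")
  }
  invisible(cfg)
}

# split a total over sites with seeded lognormal weights, min 2 per site
split_total <- function(total, n_sites, spread = 0.45) {
  w <- exp(rnorm(n_sites, 0, spread))
  n <- pmax(2L, as.integer(round(total * w / sum(w))))
  # nudge to exact total
  delta <- total - sum(n)
  i <- 1L
  while (delta != 0L) {
    j <- (i - 1L) %% n_sites + 1L
    step <- sign(delta)
    if (n[j] + step >= 2L) {
      n[j] <- n[j] + step
      delta <- delta - step
    }
    i <- i + 1L
  }
  n
}

#' Generate a synthetic multi-site case-control consortium
#'
#' Draws a consortium with the statistical structure the analysis pipeline
#' assumes. For site s and measure m the subject-level model is
#' \deqn{Y = \mu_m + b_{s,m} + \beta_{age,m}\,(age - 45) + \beta_{sex,m}\,sex
#'   + \beta_{icv,m}\,(ICV - \bar{ICV}) + \delta_{s,m}\,Dx\,\sigma_m +
#'   \epsilon,\quad \epsilon \sim N(0, \sigma_m^2),}
#' with site intercepts \eqn{b_{s,m} \sim N(0, (f \mu_m)^2)} and
#' heterogeneous true effects
#' \eqn{\delta_{s,m} \sim N(\delta_m, \tau^2)}. Age is drawn from
#' site-specific normals (site means U(35, 55), SD 10, truncated to
#' [18, 80]), sex is Bernoulli(0.5) unless the site is listed in
#' `single_sex_sites`, and ICV is normal with a male shift. Clinical fields
#' (episode status, age of onset, severity scores, medication flags,
#' remission) are drawn per the configured clinical mix for patients and
#' left missing for controls. Left/right asymmetry is not modeled: volumes
#' are emitted directly as the (L+R)/2 mean.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return An object of class `consortium`: list with `subjects` (subject
#'   tibble across sites), `sites` (site metadata and moderators, with
#'   moderator percentages computed from the realized sample), and `truth`
#'   (the per-site true standardized effects `delta_site`, a sites x
#'   measures matrix).
#' @examples
#' sim <- simulate_consortium(sim_config(
#'   n_sites = 3, n_cases_total = 30,
#'   n_controls_total = 60, seed = 42
#' ))
#' dplyr::count(sim$subjects, site_id, diagnosis)
#' @export
simulate_consortium <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(seed %||% config$seed)
  rois <- roi_names()
  vols <- roi_names(include_icv = FALSE)
  k <- config$n_sites

  n_cases <- split_total(config$n_cases_total, k)
  n_controls <- split_total(config$n_controls_total, k)
  site_ids <- sprintf("site%02d", seq_len(k))

  # site-level parameters
  site_age_mean <- runif(k, 35, 55)
  field_strength <- sample(c(1.5, 3), k, replace = TRUE, prob = c(0.3, 0.7))
  software_version <- sample(c("4.5", "5.0", "5.1", "5.3"), k, replace = TRUE)
  pct_ad <- runif(k, 30, 85)
  pct_ap <- runif(k, 0, 25)
  pct_acute <- runif(k, 50, 95)
  pct_anx <- runif(k, 10, 60)
  has_hdrs <- rbinom(k, 1, config$prob_scale) == 1
  has_bdi <- rbinom(k, 1, config$prob_scale) == 1

  # true standardized effect per site x measure
  delta_site <- matrix(
    rnorm(k * length(rois), rep(config$delta, each = k), config$tau),
    nrow = k, dimnames = list(site_ids, rois)
  )
  me <- config$moderator_effect
  if (!is.null(me)) {
    # centering constant only; the slope is injected per site against the
    # realized moderator value so that meta-regression sees no
    # errors-in-x attenuation
    me_center <- switch(me$moderator,
      pct_antipsychotic = mean(pct_ap), pct_antidepressant = mean(pct_ad),
      pct_acute = mean(pct_acute), pct_comorbid_anxiety = mean(pct_anx),
      mean_age = mean(site_age_mean), field_strength = mean(field_strength),
      abort(paste0("unknown moderator: ", me$moderator),
        class = "sitemeta_config_error"
      )
    )
  }

  site_intercept <- matrix(
    rnorm(
      k * length(rois), 0,
      rep(config$site_intercept_sd_frac * config$roi_mean, each = k)
    ),
    nrow = k, dimnames = list(site_ids, rois)
  )

  subjects <- vector("list", k)
  site_rows <- vector("list", k)
  for (s in seq_len(k)) {
    n1 <- n_cases[s]
    n0 <- n_controls[s]
    n <- n1 + n0
    dx <- c(rep(1L, n1), rep(0L, n0))
    age <- pmin(80, pmax(18, rnorm(n, site_age_mean[s], 10)))
    sex <- if (s %in% config$single_sex_sites) {
      rep(s %% 2L, n)
    } else {
      rbinom(n, 1, 0.5)
    }

    # recurrence / onset joint mix; patients scanned at <= 22 are
    # necessarily early onset (onset cannot exceed scan age), so the
    # early-onset probability among the rest is adjusted to keep the
    # configured marginal
    age1 <- age[seq_len(n1)]
    p_early <- config$pct_early_onset / 100
    p_rec <- config$pct_recurrent / 100
    p_rec_early <- config$pct_early_recurrent / 100
    p_rec_late <- if (p_early < 1) {
      min(1, max(0, (p_rec - p_early * p_rec_early) / (1 - p_early)))
    } else {
      p_rec_early
    }
    forced <- age1 <= 22
    p_adj <- if (n1 > sum(forced)) {
      min(1, max(0, (p_early * n1 - sum(forced)) / (n1 - sum(forced))))
    } else {
      1
    }
    early <- as.integer(forced)
    early[!forced] <- rbinom(n1 - sum(forced), 1, p_adj)
    rec <- rbinom(n1, 1, ifelse(early == 1, p_rec_early, p_rec_late))
    onset <- numeric(n1)
    is_e <- early == 1
    onset[is_e] <- runif(sum(is_e), 12, pmin(21, age1[is_e]))
    onset[!is_e] <- runif(sum(!is_e), 22, age1[!is_e])
    onset <- pmin(round(onset, 1), age1)
    # a sliver of missing clinical data exercises listwise deletion
    miss_clin <- runif(n1) < 0.02
    episode <- ifelse(rec == 1, "recurrent", "first")
    episode[miss_clin] <- NA_character_
    onset[miss_clin] <- NA_real_

    # medication and remission flags precede volume generation so that an
    # injected moderator effect can use the realized site percentage
    on_ad <- rbinom(n1, 1, pct_ad[s] / 100)
    on_ap <- rbinom(n1, 1, pct_ap[s] / 100)
    remit <- rbinom(n1, 1, 1 - pct_acute[s] / 100)
    if (!is.null(me)) {
      x_real <- switch(me$moderator,
        pct_antipsychotic = 100 * mean(on_ap),
        pct_antidepressant = 100 * mean(on_ad),
        pct_acute = 100 * mean(1 - remit),
        pct_comorbid_anxiety = pct_anx[s],
        mean_age = mean(age), field_strength = field_strength[s]
      )
      delta_site[s, me$roi] <- delta_site[s, me$roi] +
        me$beta * (x_real - me_center)
    }

    icv <- rnorm(n, 1.42e6 + 1.1e5 * sex, config$roi_sd[["icv"]]) +
      delta_site[s, "icv"] * dx * config$roi_sd[["icv"]]
    icv <- pmax(icv, 8e5)

    dat <- tibble::tibble(
      subject_id = sprintf("%s_%04d", site_ids[s], seq_len(n)),
      site_id = site_ids[s],
      diagnosis = dx, age = age, sex = sex, icv = icv
    )
    resid_std <- matrix(rnorm(n * length(vols)), nrow = n)
    colnames(resid_std) <- vols
    for (m in vols) {
      delta_m <- delta_site[s, m] * dx
      if (!is.null(config$delta_recurrent)) {
        delta_m <- delta_m + config$delta_recurrent[[m]] *
          dx * c(ifelse(is.na(episode), 0, rec), rep(0, n0))
      }
      y <- config$roi_mean[[m]] + site_intercept[s, m] +
        config$beta_age[[m]] * (age - 45) +
        config$beta_sex[[m]] * sex +
        config$beta_icv[[m]] * (icv - 1.5e6) +
        delta_m * config$roi_sd[[m]] +
        resid_std[, m] * config$roi_sd[[m]]
      y <- pmax(y, 1)
      if (config$missing_roi_rate > 0) {
        y[runif(n) < config$missing_roi_rate] <- NA_real_
      }
      dat[[m]] <- y
    }
    dat$scanner_id <- "scanner1"

    sev_noise <- function() {
      z <- rnorm(n1)
      if (!is.null(config$severity_assoc)) {
        sa <- config$severity_assoc
        zr <- resid_std[seq_len(n1), sa$roi]
        z <- sa$r * zr + sqrt(1 - sa$r^2) * z
      }
      z
    }
    hdrs <- if (has_hdrs[s]) {
      pmin(52, pmax(0, round(18 + 6 * sev_noise())))
    } else {
      rep(NA_real_, n1)
    }
    bdi <- if (has_bdi[s]) {
      pmin(63, pmax(0, round(22 + 9 * sev_noise())))
    } else {
      rep(NA_real_, n1)
    }
    pad <- function(x) c(x, rep(NA, n0))
    dat$episode_status <- c(episode, rep(NA_character_, n0))
    dat$age_of_onset <- pad(onset)
    dat$hdrs17 <- pad(hdrs)
    dat$bdi_ii <- pad(bdi)
    dat$on_antidepressant <- pad(on_ad)
    dat$on_antipsychotic <- pad(on_ap)
    dat$remitted <- pad(remit)
    subjects[[s]] <- dat

    site_rows[[s]] <- tibble::tibble(
      site_id = site_ids[s], n_cases = n1, n_controls = n0,
      field_strength = field_strength[s],
      software_version = software_version[s],
      mean_age = mean(age),
      pct_antidepressant = 100 * mean(on_ad),
      pct_antipsychotic = 100 * mean(on_ap),
      pct_acute = 100 * mean(1 - remit),
      pct_comorbid_anxiety = pct_anx[s],
      pct_remitted = 100 * mean(remit),
      pct_recurrent = 100 * mean(rec[!miss_clin]),
      has_hdrs17 = has_hdrs[s], has_bdi_ii = has_bdi[s]
    )
  }
  structure(
    list(
      subjects = dplyr::bind_rows(subjects),
      sites = dplyr::bind_rows(site_rows),
      truth = list(
        delta_site = delta_site, delta = config$delta, tau = config$tau
      ),
      config = config
    ),
    class = "consortium"
  )
}

#' @export
print.consortium <- function(x, ...) {
  cat(
    "<consortium> ", nrow(x$sites), " sites, ",
    sum(x$subjects$diagnosis == 1), " patients / ",
    sum(x$subjects$diagnosis == 0), " controls\n",
    sep = ""
  )
  invisible(x)
}
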