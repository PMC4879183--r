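# Between-site variance estimators -----------------------------------------

# Generalized DerSimonian-Laird (method of moments) for y = X b + u + e,
# u ~ N(0, tau2), e_i ~ N(0, v_i). With W = diag(1/v) and
# P = W - WX(X'WX)^{-1}X'W, E[y'Py] = (k - p) + tau2 tr(P), so
# tau2 = max(0, (y'Py - (k - p)) / tr(P)). For an intercept-only X this is
# the classical DL estimator (Q - (k-1)) / (sum w - sum w^2 / sum w).
dl_tau2 <- function(y, v, X = matrix(1, length(y))) {
  w <- 1 / v
  P <- p_matrix(w, X)
  q <- drop(crossprod(y, P %*% y))
  raw <- (q - (length(y) - ncol(X))) / sum(diag(P))
  list(tau2 = max(0, raw), truncated = raw < 0)
}

p_matrix <- function(w, X) {
  WX <- w * X
  diag(w, length(w)) - WX %*% solve(crossprod(X, WX)) %*% t(WX)
}

# REML estimate of tau2 by Fisher scoring on the restricted log-likelihood;
# tolerance 1e-8, at most `max_iter` iterations, fallback to the moment
# estimator with a warning on non-convergence.
reml_tau2 <- function(y, v, X = matrix(1, length(y)), tol = 1e-8,
                      max_iter = 100) {
  tau2 <- dl_tau2(y, v, X)$tau2
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    P <- p_matrix(w, X)
    Py <- drop(P %*% y)
    score <- -0.5 * sum(diag(P)) + 0.5 * sum(Py^2)
    info <- 0.5 * sum(P * P)
    tau2_new <- max(0, tau2 + score / info)
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  if (!converged) {
    warn("REML estimation of tau^2 did not converge; falling back to DL",
      class = "sitemeta_reml_warning"
    )
    tau2 <- dl_tau2(y, v, X)$tau2
  }
  tau2
}

# Heterogeneity -------------------------------------------------------------

#' Heterogeneity statistics for a set of effect sizes
#'
#' Cochran's Q under fixed-effect weights `1/v_i`,
#' \eqn{Q = \sum w_i (d_i - \bar d_{FE})^2}, and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \cdot 100} (0 when Q = 0), the percent
#' of total variability attributable to between-site heterogeneity.
#'
#' @param effects Tibble with columns `value` and `variance` (one row per
#'   site), as from [site_effect_sizes()].
#' @return List with `q_stat` and `i2`.
#' @examples
#' heterogeneity(tibble::tibble(value = c(0, 1), variance = c(0.5, 0.5)))
#' @export
heterogeneity <- function(effects) {
  check_effects(effects, k_min = 2)
  w <- 1 / effects$variance
  fe <- sum(w * effects$value) / sum(w)
  q <- sum(w * (effects$value - fe)^2)
  k <- nrow(effects)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(q_stat = q, i2 = i2)
}

check_effects <- function(effects, k_min = 2) {
  if (!is.data.frame(effects) || !all(c("value", "variance") %in% names(effects))) {
    abort_domain("effects must be a tibble with columns value and variance")
  }
  if (nrow(effects) < k_min) {
    abort(
      paste0("need at least ", k_min, " effects, got ", nrow(effects)),
      class = "sitemeta_pooling_error"
    )
  }
  if (any(!is.finite(effects$value)) || any(!is.finite(effects$variance)) ||
    any(effects$variance <= 0)) {
    abort_domain("all effect values must be finite and variances positive")
  }
  if ("metric" %in% names(effects) &&
    length(unique(effects$metric)) > 1) {
    abort_domain("effects mix metrics; pool one metric at a time")
  }
  invisible(effects)
}

# Pooling -------------------------------------------------------------------

#' Inverse-variance-weighted random-effects pooling
#'
#' Pools per-site effect sizes under the random-effects model
#' \eqn{d_i = \delta + u_i + e_i}, \eqn{u_i \sim N(0, \tau^2)},
#' \eqn{e_i \sim N(0, v_i)}. The between-site variance is estimated by REML
#' (Fisher scoring, tolerance 1e-8, at most 100 iterations, DL fallback with
#' a warning) or by the DerSimonian-Laird moment estimator; the pooled
#' effect uses weights \eqn{w_i^* = 1/(v_i + \tau^2)}, with
#' \eqn{se = 1/\sqrt{\sum w_i^*}}, a Wald 95% CI and a two-sided normal
#' p-value. Heterogeneity is reported as Q (fixed-effect weights), `tau2`
#' and `I^2`; both tau^2 and I^2 are truncated at zero, with truncation
#' recorded in `$notes`.
#'
#' Partial correlations (`metric == "pearson_r"`) are pooled on the raw r
#' scale by default, using the per-site variances carried in the effect
#' table; `r_scale = "fisher_z"` instead pools `atanh(r)` with variance
#' `1/(n - m - 3)` and back-transforms the estimate and CI.
#'
#' @param effects Tibble of per-site effects of a single metric/contrast/
#'   measure: columns `value`, `variance` (and for correlations `n`,
#'   `n_partialled`), as from [site_effect_sizes()] or [severity_model()].
#' @param tau2_method `"REML"` (default) or `"DL"`.
#' @param level Confidence level (default 0.95).
#' @param r_scale Pooling scale for correlations: `"raw"` (default) or
#'   `"fisher_z"`.
#' @return An object of class `meta_result`; see [tidy.meta_result()].
#' @examples
#' es <- tibble::tibble(value = c(0.1, 0.3, 0.8), variance = rep(0.04, 3))
#' pool_random_effects(es, tau2_method = "DL")
#' @export
pool_random_effects <- function(effects, tau2_method = c("REML", "DL"),
                                level = 0.95, r_scale = c("raw", "fisher_z")) {
  tau2_method <- match.arg(tau2_method)
  r_scale <- match.arg(r_scale)
  check_effects(effects, k_min = 2)
  metric <- if ("metric" %in% names(effects)) effects$metric[1] else "cohens_d"
  notes <- character(0)

  y <- effects$value
  v <- effects$variance
  transformed <- FALSE
  if (metric == "pearson_r" && r_scale == "fisher_z") {
    if (!all(c("n", "n_partialled") %in% names(effects))) {
      abort_domain("fisher_z pooling needs columns n and n_partialled")
    }
    y <- atanh(y)
    v <- 1 / (effects$n - effects$n_partialled - 3)
    if (any(v <= 0)) abort_domain("n - n_partialled - 3 must be positive")
    transformed <- TRUE
  }

  het <- heterogeneity(tibble::tibble(value = y, variance = v))
  if (tau2_method == "DL") {
    dl <- dl_tau2(y, v)
    tau2 <- dl$tau2
    if (dl$truncated) notes <- c(notes, "tau2 truncated at 0")
  } else {
    tau2 <- reml_tau2(y, v)
  }
  k <- length(y)
  if (het$q_stat > 0 && (het$q_stat - (k - 1)) / het$q_stat < 0) {
    notes <- c(notes, "I2 truncated at 0")
  }

  w <- 1 / (v + tau2)
  pooled <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  ci <- wald_ci(pooled, se, level)
  z <- pooled / se
  if (transformed) {
    pooled <- tanh(pooled)
    ci <- tibble::tibble(
      ci_low = tanh(ci$ci_low), ci_high = tanh(ci$ci_high)
    )
  }

  pct <- if ("pct_difference" %in% names(effects) &&
    any(!is.na(effects$pct_difference))) {
    weighted.mean(effects$pct_difference, 1 / effects$variance, na.rm = TRUE)
  } else {
    NA_real_
  }
  structure(
    list(
      roi = first_or_na(effects, "roi"),
      contrast = first_or_na(effects, "contrast"),
      metric = metric,
      pooled = pooled, se = se,
      ci_low = ci$ci_low, ci_high = ci$ci_high, level = level,
      z = z, p_value = two_sided_p(z),
      q_stat = het$q_stat, tau2 = tau2, i2 = het$i2, k = k,
      n_cases = sum_or_na(effects, "n_cases"),
      n_controls = sum_or_na(effects, "n_controls"),
      n = sum_or_na(effects, "n"),
      pct_difference = pct,
      tau2_method = tau2_method, r_scale = r_scale,
      notes = notes, effects = effects
    ),
    class = "meta_result"
  )
}

first_or_na <- function(x, col) {
  if (col %in% names(x)) x[[col]][1] else NA_character_
}

sum_or_na <- function(x, col) {
  if (col %in% names(x)) sum(x[[col]], na.rm = TRUE) else NA_integer_
}

#' @export
print.meta_result <- function(x, ...) {
  cat(
    "<meta_result> ", x$metric,
    if (!is.na(x$roi)) paste0(" | ", x$roi),
    if (!is.na(x$contrast)) paste0(" | ", x$contrast), "\n",
    "  pooled = ", format(x$pooled, digits = 4),
    " (se ", format(x$se, digits = 4), "), ",
    100 * x$level, "% CI [", format(x$ci_low, digits = 4), ", ",
    format(x$ci_high, digits = 4), "], p = ", format(x$p_value, digits = 3),
    "\n  k = ", x$k, ", Q = ", format(x$q_stat, digits = 4),
    ", tau2 = ", format(x$tau2, digits = 4), " (", x$tau2_method,
    "), I2 = ", format(x$i2, digits = 3), "%\n",
    sep = ""
  )
  invisible(x)
}

#' Pool a direct patient-group contrast
#'
#' Pools per-site effect sizes from a direct two-patient-group regression
#' (recurrent = 1 vs first = 0, or early = 1 vs late = 0, same covariates as
#' the primary model) exactly as [pool_random_effects()]; exposed separately
#' because group-vs-group questions must be answered by this direct
#' contrast, not by comparing two stratum-vs-control pooled effects.
#'
#' @inheritParams pool_random_effects
#' @return A `meta_result`.
#' @export
compare_groups <- function(effects, tau2_method = c("REML", "DL"),
                           level = 0.95) {
  pool_random_effects(effects, tau2_method = tau2_method, level = level)
}

# Meta-regression -----------------------------------------------------------

#' Single-moderator meta-regression
#'
#' Mixed-effects meta-regression
#' \eqn{d_i = \beta_0 + \beta_1 x_i + u_i + e_i}, with
#' \eqn{u_i \sim N(0, \tau^2)} estimated by REML and \eqn{\beta} by weighted
#' least squares with weights \eqn{1/(v_i + \tau^2)}; the moderator slope is
#' tested with a two-sided Wald z-test. Requires `k >= 3` sites (intercept,
#' slope and tau^2 must all be estimable) and a non-constant moderator.
#'
#' @param effects Tibble of per-site effects (`value`, `variance`).
#' @param moderator Numeric vector of site-level moderator values, aligned
#'   with the rows of `effects`. `NA` moderator values drop the site (with a
#'   run-log entry in the pipeline wrapper).
#' @param moderator_name Label stored in the result.
#' @return Object of class `meta_regression_result`: `beta` (slope per
#'   moderator unit), `se_beta`, `p_value`, `intercept`, `residual_tau2`,
#'   `k`.
#' @examples
#' es <- tibble::tibble(
#'   value = c(0.05, 0.1, 0.2, 0.3),
#'   variance = rep(0.02, 4)
#' )
#' meta_regress(es, moderator = c(0, 25, 50, 100), moderator_name = "pct_users")
#' @export
meta_regress <- function(effects, moderator, moderator_name = "moderator") {
  check_effects(effects, k_min = 1)
  if (length(moderator) != nrow(effects)) {
    abort_domain("moderator must have one value per effect")
  }
  keep <- !is.na(moderator)
  effects <- effects[keep, , drop = FALSE]
  moderator <- moderator[keep]
  if (nrow(effects) < 3) {
    abort(
      paste0(
        "meta-regression needs >= 3 sites (intercept + slope + tau2), got ",
        nrow(effects)
      ),
      class = "sitemeta_estimability_error"
    )
  }
  if (length(unique(moderator)) < 2) {
    abort("moderator is constant across sites",
      class = "sitemeta_collinearity_error"
    )
  }
  y <- effects$value
  v <- effects$variance
  X <- cbind(intercept = 1, moderator = moderator)
  tau2 <- reml_tau2(y, v, X)
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X, w * X)
  cov_b <- solve(XtWX)
  beta <- drop(cov_b %*% crossprod(X, w * y))
  se <- sqrt(diag(cov_b))
  z <- beta[2] / se[2]
  structure(
    list(
      moderator_name = moderator_name,
      roi = first_or_na(effects, "roi"),
      contrast = first_or_na(effects, "contrast"),
      beta = unname(beta[2]), se_beta = unname(se[2]),
      p_value = two_sided_p(z),
      intercept = unname(beta[1]), se_intercept = unname(se[1]),
      residual_tau2 = tau2, k = nrow(effects)
    ),
    class = "meta_regression_result"
  )
}

#' @export
print.meta_regression_result <- function(x, ...) {
  cat(
    "<meta_regression> ", x$moderator_name,
    if (!is.na(x$roi)) paste0(" on ", x$roi), "\n",
    "  beta = ", format(x$beta, digits = 4),
    " (se ", format(x$se_beta, digits = 4),
    "), p = ", format(x$p_value, digits = 3),
    ", residual tau2 = ", format(x$residual_tau2, digits = 4),
    ", k = ", x$k, "\n",
    sep = ""
  )
  invisible(x)
}
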