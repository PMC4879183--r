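# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# OLS by the normal equations: solve(X'X) X'y, with t-stats from the
# unscaled covariance diag.
normal_equations_fit <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  list(beta = drop(beta), se = se, t = drop(beta) / se, df = df)
}

# Classical DerSimonian-Laird, transcribed directly from the moment formula.
dl_by_hand <- function(d, v) {
  w <- 1 / v
  fe <- sum(w * d) / sum(w)
  q <- sum(w * (d - fe)^2)
  k <- length(d)
  max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# Restricted log-likelihood for the intercept-only random-effects model;
# used for grid-search verification of the REML estimate.
restricted_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) -
    0.5 * sum(w * (y - mu)^2)
}

grid_reml <- function(y, v, upper = 1, step = 1e-5) {
  grid <- seq(0, upper, by = step)
  grid[which.max(vapply(grid, restricted_loglik, numeric(1), y = y, v = v))]
}

# Direct pooled-SD standardized mean difference (no covariates).
direct_smd <- function(y1, y0) {
  sp <- sqrt(((length(y1) - 1) * var(y1) + (length(y0) - 1) * var(y0)) /
    (length(y1) + length(y0) - 2))
  (mean(y1) - mean(y0)) / sp
}

# Small scaled-down consortium used across Monte-Carlo tests: the study's
# site count with per-site sizes reduced to keep the suite fast.
small_config <- function(seed, ...) {
  sim_config(
    n_sites = 15, n_cases_total = 450, n_controls_total = 900,
    missing_roi_rate = 0, seed = seed, ...
  )
}
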