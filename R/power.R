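#' Achieved power of the two-sided two-sample t-test
#'
#' Exact noncentral-t power for the two-sided pooled-variance two-sample
#' t-test: with `df = n1 + n2 - 2` and noncentrality
#' `ncp = d * sqrt(n1 n2 / (n1 + n2))`, the power is
#' `P(|T| > t_crit)` under the noncentral t. At `d = 0` this returns the
#' size of the test, `alpha`.
#'
#' @param d Standardized mean difference (Cohen's d).
#' @param n1,n2 Group sizes, each `>= 2`.
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @return Power in (0, 1).
#' @examples
#' achieved_power(0.3, 50, 50)
#' @export
achieved_power <- function(d, n1, n2, alpha = 0.05) {
  check_alpha(alpha)
  if (n1 < 2 || n2 < 2) abort_domain("group sizes must be >= 2")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

check_alpha <- function(alpha, power = NULL) {
  if (alpha <= 0 || alpha >= 1) abort_domain("alpha must be in (0, 1)")
  if (!is.null(power) && (power <= alpha || power >= 1)) {
    abort_domain("power must be in (alpha, 1)")
  }
  invisible(TRUE)
}

#' Minimum detectable effect size at fixed group sizes
#'
#' The smallest Cohen's d detectable with the requested power by a
#' two-sided two-sample test at the given group sizes. The default
#' (`method = "nct"`) inverts the exact noncentral-t power function
#' ([achieved_power()]); `method = "normal"` uses the large-sample
#' approximation
#' \deqn{d = (z_{1-\alpha/2} + z_{power}) \sqrt{1/n_1 + 1/n_2},}
#' which for large unequal groups differs from the exact solution in the
#' fourth decimal.
#'
#' @param n1,n2 Group sizes, each `>= 2`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power in `(alpha, 1)` (default 0.80).
#' @param method `"nct"` (exact, default) or `"normal"`.
#' @return Minimum detectable Cohen's d.
#' @examples
#' min_detectable_d(1728, 7199)
#' @export
min_detectable_d <- function(n1, n2, alpha = 0.05, power = 0.80,
                             method = c("nct", "normal")) {
  method <- match.arg(method)
  check_alpha(alpha, power)
  if (n1 < 2 || n2 < 2) abort_domain("group sizes must be >= 2")
  if (method == "normal") {
    return((qnorm(1 - alpha / 2) + qnorm(power)) * sqrt(1 / n1 + 1 / n2))
  }
  upper <- 2 * (qnorm(1 - alpha / 2) + qnorm(power)) * sqrt(1 / n1 + 1 / n2)
  uniroot(
    function(d) achieved_power(d, n1, n2, alpha) - power,
    lower = 0, upper = max(upper, 1e-3), tol = 1e-12
  )$root
}

#' Required per-group sample size for a target effect
#'
#' Smallest integer n per group such that the two-sided two-sample t-test
#' attains the target power for effect size d, using exact noncentral-t
#' power with `df = 2n - 2` and noncentrality `d * sqrt(n/2)`, solved by
#' bisection (default). `method = "normal"` reports the large-sample
#' approximation `ceiling(2 ((z_{1-alpha/2} + z_{power})/d)^2)`, which runs
#' about one subject below the exact answer.
#'
#' @param d Target Cohen's d, nonzero.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param method `"nct"` (exact, default) or `"normal"`.
#' @return Integer subjects per group.
#' @examples
#' required_n_per_group(0.2)
#' @export
required_n_per_group <- function(d, alpha = 0.05, power = 0.80,
                                 method = c("nct", "normal")) {
  method <- match.arg(method)
  check_alpha(alpha, power)
  if (d == 0) abort_domain("d = 0 requires infinite n")
  d <- abs(d)
  if (method == "normal") {
    return(as.integer(ceiling(2 * ((qnorm(1 - alpha / 2) + qnorm(power)) / d)^2)))
  }
  hi <- 4L
  while (achieved_power(d, hi, hi, alpha) < power) {
    hi <- hi * 2L
    if (hi > 1e8) abort_domain("required n exceeds 1e8; effect too small")
  }
  lo <- max(2L, hi %/% 2L)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (achieved_power(d, mid, mid, alpha) >= power) hi <- mid else lo <- mid
  }
  if (achieved_power(d, lo, lo, alpha) >= power) lo else hi
}
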