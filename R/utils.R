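#' Wald confidence interval
#'
#' Normal-approximation (Wald) interval `estimate +/- z * se`, the interval
#' used for all pooled effects and meta-regression coefficients.
#'
#' @param estimate Point estimate(s).
#' @param se Standard error(s), `> 0`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `ci_low`, `ci_high`.
#' @examples
#' wald_ci(-0.144, 0.041)
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  stopifnot(level > 0, level < 1, all(se > 0))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(ci_low = estimate - z * se, ci_high = estimate + z * se)
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))

abort_domain <- function(message, ...) {
  abort(message, class = "sitemeta_domain_error", ...)
}

abort_contrast <- function(message, reason, ...) {
  abort(message, class = "sitemeta_contrast_error", reason = reason, ...)
}

# empty exclusion-log skeleton shared by effect computation and pipelines
empty_run_log <- function() {
  tibble::tibble(
    site_id = character(), roi = character(), contrast = character(),
    reason = character()
  )
}

#' Retrieve the run log of a pipeline result
#'
#' Every site x measure combination excluded from a contrast (too few group
#' members, rank-deficient design, missing severity scale, ...) is recorded
#' exactly once with a machine-readable reason code rather than silently
#' dropped.
#'
#' @param x A result returned by [run_primary()], [run_stratified()],
#'   [run_severity()], [run_moderators()] or [site_effect_sizes()].
#' @return A tibble with columns `site_id`, `roi`, `contrast`, `reason`.
#' @export
run_log <- function(x) {
  attr(x, "run_log") %||% empty_run_log()
}
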