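#' Tidy a pooled meta-analysis result
#'
#' @param x A `meta_result` from [pool_random_effects()].
#' @param ... Unused.
#' @return One-row tibble: `roi`, `contrast`, `metric`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `z`, `p_value`.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  tibble::tibble(
    roi = x$roi, contrast = x$contrast, metric = x$metric,
    estimate = x$pooled, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
    z = x$z, p_value = x$p_value
  )
}

#' Heterogeneity summary of a pooled result
#'
#' @inheritParams tidy.meta_result
#' @return One-row tibble: `k`, `q_stat`, `tau2`, `i2`, `tau2_method`,
#'   `n_cases`, `n_controls`.
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    k = x$k, q_stat = x$q_stat, tau2 = x$tau2, i2 = x$i2,
    tau2_method = x$tau2_method,
    n_cases = x$n_cases, n_controls = x$n_controls
  )
}

#' Tidy a meta-regression result
#'
#' @param x A `meta_regression_result` from [meta_regress()].
#' @param ... Unused.
#' @return Two-row tibble (intercept and moderator slope) with `term`,
#'   `estimate`, `se`, `p_value`.
#' @method tidy meta_regression_result
#' @export
tidy.meta_regression_result <- function(x, ...) {
  tibble::tibble(
    moderator = x$moderator_name, roi = x$roi,
    term = c("intercept", x$moderator_name),
    estimate = c(x$intercept, x$beta),
    se = c(x$se_intercept, x$se_beta),
    p_value = c(NA_real_, x$p_value)
  )
}

#' @rdname tidy.meta_regression_result
#' @method glance meta_regression_result
#' @export
glance.meta_regression_result <- function(x, ...) {
  tibble::tibble(
    moderator = x$moderator_name, roi = x$roi, beta = x$beta,
    se_beta = x$se_beta, p_value = x$p_value,
    residual_tau2 = x$residual_tau2, k = x$k
  )
}

#' Forest plot of a pooled result
#'
#' Per-site effect estimates with 95% intervals, point size proportional to
#' the random-effects weight, and the pooled estimate with its interval at
#' the bottom.
#'
#' @param object A `meta_result` from [pool_random_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  es <- object$effects
  z <- qnorm(1 - (1 - object$level) / 2)
  lab <- if ("site_id" %in% names(es)) es$site_id else
    paste0("site ", seq_len(nrow(es)))
  dat <- tibble::tibble(
    label = factor(c(lab, "pooled"), levels = rev(c(lab, "pooled"))),
    estimate = c(es$value, object$pooled),
    low = c(es$value - z * sqrt(es$variance), object$ci_low),
    high = c(es$value + z * sqrt(es$variance), object$ci_high),
    weight = c(
      1 / (es$variance + object$tau2),
      sum(1 / (es$variance + object$tau2))
    ),
    pooled = c(rep(FALSE, nrow(es)), TRUE)
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$estimate, y = .data$label, shape = .data$pooled)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$low, xmax = .data$high),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18)) +
    ggplot2::guides(size = "none", shape = "none") +
    ggplot2::labs(
      x = paste0(
        object$metric,
        if (!is.na(object$roi)) paste0(" (", object$roi, ")")
      ),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Effect-size panel across measures
#'
#' Pooled effect and 95% CI per measure for one or more result tables (as
#' from [run_primary()] / [run_stratified()]), faceted by contrast when
#' several are bound together.
#'
#' @param results Result tibble(s) with columns `roi`, `contrast`,
#'   `cohens_d`, `ci_low`, `ci_high`.
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(results) {
  stopifnot(all(c("roi", "cohens_d", "ci_low", "ci_high") %in% names(results)))
  results$roi <- factor(results$roi, levels = rev(roi_names()))
  p <- ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$cohens_d, y = .data$roi)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.25
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Cohen's d (patients - controls)", y = NULL) +
    ggplot2::theme_minimal()
  if ("contrast" %in% names(results) &&
    length(unique(results$contrast)) > 1) {
    p <- p + ggplot2::facet_wrap(~contrast)
  }
  p
}
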