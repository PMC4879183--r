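test_that("site model matches the normal-equations oracle on a small fixture", {
  set.seed(101)
  n <- 12
  site <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n), site_id = "fix",
    diagnosis = rep(c(1L, 0L), each = n / 2),
    age = round(runif(n, 20, 60), 1),
    sex = rep_len(c(0, 1), n),
    # well-conditioned units keep the normal-equations comparison meaningful
    icv = round(rnorm(n, 1.5, 0.1), 5),
    hippocampus = round(rnorm(n, 4.1, 0.3), 5)
  )
  fit <- fit_site_model(site, "hippocampus")
  X <- cbind(1, site$diagnosis, site$age, site$sex, site$icv)
  oracle <- normal_equations_fit(X, site$hippocampus)
  expect_lt(abs(fit$coefficient - oracle$beta[2]), 1e-10)
  expect_lt(abs(fit$t_stat - oracle$t[2]), 1e-10)
  expect_equal(fit$df_residual, oracle$df)
  expect_equal(fit$n_cases, 6)
  expect_equal(fit$n_controls, 6)
})

test_that("an outcome that is a pure covariate function has zero group effect", {
  set.seed(77)
  site <- make_fixture("tiny_site")
  site <- dplyr::bind_rows(site, site |>
    dplyr::mutate(subject_id = paste0(subject_id, "b"), age = age + 1))
  # covariate signal plus noise orthogonalized against the full design:
  # the diagnosis coefficient is then exactly zero
  X <- cbind(1, site$diagnosis, site$age, site$sex, site$icv)
  e <- stats::resid(lm(rnorm(nrow(site), 0, 50) ~ X))
  site$hippocampus <- 2000 + 3 * site$age + 50 * site$sex +
    0.001 * site$icv + e
  fit <- fit_site_model(site, "hippocampus")
  expect_lt(abs(fit$coefficient), 1e-8)
  expect_lt(abs(fit$t_stat), 1e-8)
})

test_that("effect sizes are invariant to shifts and positive rescaling", {
  site <- make_fixture("two_scanner_site")
  fit <- fit_site_model(site, "hippocampus")

  shifted <- site
  shifted$hippocampus <- shifted$hippocampus + 1000
  fit_shift <- fit_site_model(shifted, "hippocampus")
  expect_equal(fit_shift$t_stat, fit$t_stat, tolerance = 1e-10)
  expect_equal(fit_shift$coefficient, fit$coefficient, tolerance = 1e-8)

  # mm^3 -> cm^3 on the outcome, plus constant shifts of covariates
  scaled <- site
  scaled$hippocampus <- scaled$hippocampus / 1000
  scaled$age <- scaled$age - 40
  scaled$icv <- scaled$icv - 1.4e6
  fit_scaled <- fit_site_model(scaled, "hippocampus")
  d1 <- cohens_d_from_t(fit$t_stat, fit$n_cases, fit$n_controls, fit$df_residual)
  d2 <- cohens_d_from_t(
    fit_scaled$t_stat, fit_scaled$n_cases, fit_scaled$n_controls,
    fit_scaled$df_residual
  )
  expect_equal(d1$value, d2$value, tolerance = 1e-10)
  expect_equal(d1$variance, d2$variance, tolerance = 1e-10)
})

test_that("icv outcome drops the icv covariate; scanner dummies enter when needed", {
  site <- make_fixture("two_scanner_site")
  fit_icv <- fit_site_model(site, "icv")
  # 1 intercept + grp + age + sex + 1 scanner dummy
  expect_equal(fit_icv$n_coef, 5)
  fit_hip <- fit_site_model(site, "hippocampus")
  expect_equal(fit_hip$n_coef, 6)

  # diagnosis t is invariant to relabeling the scanners
  relabeled <- site
  relabeled$scanner_id <- ifelse(
    relabeled$scanner_id == "scannerA", "scannerZ", "scannerY"
  )
  expect_equal(
    fit_site_model(relabeled, "hippocampus")$t_stat,
    fit_hip$t_stat,
    tolerance = 1e-10
  )
})

test_that("degenerate designs raise structured errors", {
  site <- make_fixture("tiny_site")
  no_cases <- dplyr::filter(site, diagnosis == 0)
  expect_error(
    fit_site_model(no_cases, "hippocampus"),
    class = "sitemeta_contrast_error"
  )
  const_age <- make_fixture("two_scanner_site")
  const_age$age <- 40
  err <- expect_error(
    fit_site_model(const_age, "hippocampus"),
    class = "sitemeta_singularity_error"
  )
  expect_match(conditionMessage(err), "age")
})

test_that("cohens_d_from_t implements the stated conversion and variance", {
  null <- cohens_d_from_t(0, 30, 70, 95)
  expect_equal(null$value, 0)
  expect_equal(null$variance, 100 / 2100)

  d <- cohens_d_from_t(2, 50, 50, 96)
  expect_equal(d$value, 2 * 100 / (50 * sqrt(96)), tolerance = 1e-12)
  expect_equal(round(d$value, 4), 0.4082)
  expect_equal(
    d$variance, 100 / 2500 + d$value^2 / 200,
    tolerance = 1e-12
  )
  expect_error(cohens_d_from_t(1, 10, 10, 0), class = "sitemeta_domain_error")

  g <- cohens_d_from_t(2, 50, 50, 96, hedges_correction = TRUE)
  expect_equal(g$value, d$value * (1 - 3 / (4 * 96 - 1)), tolerance = 1e-12)
})

test_that("d from the regression t agrees with the direct SMD without covariates", {
  set.seed(202)
  reps <- 50
  gap <- numeric(reps)
  for (i in seq_len(reps)) {
    y1 <- rnorm(60, 0.4, 1)
    y0 <- rnorm(60, 0, 1)
    fit <- lm(y ~ grp, data = data.frame(y = c(y1, y0), grp = rep(1:0, each = 60)))
    t_val <- summary(fit)$coefficients["grp", "t value"]
    d_t <- cohens_d_from_t(t_val, 60, 60, fit$df.residual)$value
    gap[i] <- abs(d_t - direct_smd(y1, y0))
  }
  # the df factor makes the two differ at O(1/n)
  expect_lt(max(gap), 0.02)
})

test_that("partial_r_from_t is bounded, monotone, and matches hand values", {
  expect_equal(partial_r_from_t(0, 20)$value, 0)
  expect_equal(partial_r_from_t(3, 9)$value, 3 / sqrt(18), tolerance = 1e-12)
  expect_equal(partial_r_from_t(3, 9)$value, 0.7071, tolerance = 1e-4)
  ts <- seq(-30, 30, by = 0.5)
  rs <- vapply(ts, function(t) partial_r_from_t(t, 15)$value, numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_true(all(abs(rs) < 1))
  expect_error(partial_r_from_t(1, 0), class = "sitemeta_domain_error")
})

test_that("percent difference is the adjusted-means ratio and tracks the coefficient sign", {
  fit <- fit_site_model(make_fixture("tiny_site"), "hippocampus")
  manual <- 100 * (fit$adjusted_mean_cases - fit$adjusted_mean_controls) /
    fit$adjusted_mean_controls
  expect_equal(percent_difference(fit), manual)
  expect_equal(
    fit$adjusted_mean_cases - fit$adjusted_mean_controls,
    fit$coefficient,
    tolerance = 1e-8
  )
  expect_equal(100 * (3950 - 4000) / 4000, -1.25)

  set.seed(303)
  sim <- simulate_consortium(sim_config(
    n_sites = 4, n_cases_total = 120, n_controls_total = 240,
    delta = c(hippocampus = -0.4), seed = 7
  ))
  es <- site_effect_sizes(sim$subjects, rois = "hippocampus")
  expect_true(all(sign(es$pct_difference) == sign(es$value)))
})

test_that("interaction model is sex-coding symmetric and needs both sexes", {
  site <- make_fixture("two_scanner_site")
  fit <- fit_interaction_model(site, "hippocampus")
  flipped <- site
  flipped$sex <- 1 - flipped$sex
  fit_fl <- fit_interaction_model(flipped, "hippocampus")
  expect_equal(fit_fl$coefficient, -fit$coefficient, tolerance = 1e-8)
  expect_equal(abs(fit_fl$t_stat), abs(fit$t_stat), tolerance = 1e-10)

  expect_error(
    fit_interaction_model(make_fixture("single_sex_site"), "hippocampus"),
    class = "sitemeta_contrast_error"
  )
})

test_that("interaction t is centered under a no-interaction generator", {
  set.seed(404)
  tvals <- replicate(120, {
    n <- 60
    dx <- rep(1:0, each = n / 2)
    sex <- rbinom(n, 1, 0.5)
    age <- runif(n, 20, 60)
    icv <- rnorm(n, 1.5e6, 1e5)
    site <- tibble::tibble(
      subject_id = as.character(1:n), site_id = "s", diagnosis = dx,
      age = age, sex = sex, icv = icv,
      hippocampus = 4000 - 100 * dx + 50 * sex - 2 * age +
        0.002 * (icv - 1.5e6) + rnorm(n, 0, 300)
    )
    fit_interaction_model(site, "hippocampus")$t_stat
  })
  expect_lt(abs(mean(tvals)), 3 / sqrt(120)) # ~central t mean 0
  expect_lt(abs(sd(tvals) - 1), 0.3)
})

test_that("severity model composes with partial_r_from_t and skips thin sites", {
  site <- make_fixture("two_scanner_site")
  es <- severity_model(site, "hippocampus", "hdrs17")
  dat <- dplyr::filter(site, diagnosis == 1)
  fit <- lm(
    hippocampus ~ hdrs17 + age + sex + icv + factor(scanner_id),
    data = dat
  )
  t_sev <- summary(fit)$coefficients["hdrs17", "t value"]
  expect_equal(
    es$value,
    partial_r_from_t(t_sev, fit$df.residual)$value,
    tolerance = 1e-12
  )
  expect_equal(es$n, nrow(dat))
  expect_equal(es$n_partialled, 4) # age, sex, icv, scanner dummy

  expect_error(
    severity_model(make_fixture("missing_severity_site"), "hippocampus", "hdrs17"),
    class = "sitemeta_contrast_error"
  )
})

test_that("severity recovers an injected partial correlation", {
  set.seed(505)
  sim <- simulate_consortium(sim_config(
    n_sites = 15, n_cases_total = 1200, n_controls_total = 1200,
    missing_roi_rate = 0, prob_scale = 1,
    severity_assoc = list(roi = "hippocampus", r = 0.3), seed = 99
  ))
  res <- run_severity(sim$subjects, scale = "hdrs17", rois = "hippocampus")
  expect_gt(res$pearson_r, 0.3 - 3 * res$se)
  expect_lt(res$pearson_r, 0.3 + 3 * res$se)
})
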