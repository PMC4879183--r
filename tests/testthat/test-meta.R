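make_es <- function(value, variance, ...) {
  tibble::tibble(value = value, variance = variance, ...)
}

test_that("degenerate homogeneous input pools trivially", {
  es <- make_es(c(0.5, 0.5), c(0.1, 0.1))
  for (m in c("DL", "REML")) {
    res <- pool_random_effects(es, tau2_method = m)
    expect_equal(res$pooled, 0.5)
    expect_equal(res$q_stat, 0)
    expect_equal(res$tau2, 0)
    expect_equal(res$i2, 0)
    expect_equal(res$se, sqrt(0.05), tolerance = 1e-12)
  }
})

test_that("DL pooling matches the hand-executed moment computation", {
  es <- make_es(c(0.1, 0.3, 0.8), rep(0.04, 3))
  res <- pool_random_effects(es, tau2_method = "DL")
  # w = 25 each: FE mean 0.4, Q = 25 * (0.09 + 0.01 + 0.16) = 6.5,
  # tau2 = (6.5 - 2) / (75 - 1875/75) = 0.09
  expect_equal(res$q_stat, 6.5, tolerance = 1e-12)
  expect_equal(res$tau2, 0.09, tolerance = 1e-12)
  expect_equal(res$tau2, dl_by_hand(es$value, es$variance), tolerance = 1e-12)
  expect_equal(res$pooled, 0.4, tolerance = 1e-12)
  expect_equal(res$se, 1 / sqrt(3 / 0.13), tolerance = 1e-12)
})

test_that("REML tau2 matches a dense grid search of the restricted likelihood", {
  es <- make_es(c(0.1, 0.3, 0.8), rep(0.04, 3))
  res <- pool_random_effects(es, tau2_method = "REML")
  expect_lt(abs(res$tau2 - grid_reml(es$value, es$variance)), 1e-5)

  es2 <- make_es(c(-0.3, 0.05, 0.2, 0.6, -0.1), c(0.02, 0.05, 0.01, 0.08, 0.03))
  res2 <- pool_random_effects(es2, tau2_method = "REML")
  expect_lt(abs(res2$tau2 - grid_reml(es2$value, es2$variance)), 1e-5)
})

test_that("pooling agrees with an independent reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(42)
  es <- make_es(rnorm(12, -0.1, 0.2), runif(12, 0.02, 0.1))
  for (m in c("DL", "REML")) {
    ours <- pool_random_effects(es, tau2_method = m)
    ref <- metafor::rma(yi = es$value, vi = es$variance, method = m)
    expect_equal(ours$pooled, unname(ref$beta[1]), tolerance = 1e-6)
    expect_equal(ours$se, unname(ref$se), tolerance = 1e-6)
    expect_equal(ours$tau2, unname(ref$tau2), tolerance = 1e-6)
    expect_equal(ours$q_stat, unname(ref$QE), tolerance = 1e-8)
    expect_equal(ours$i2, unname(ref$I2), tolerance = 0.01)
  }
})

test_that("heterogeneity hand cases and bounds", {
  het <- heterogeneity(make_es(c(0, 1), c(0.5, 0.5)))
  expect_equal(het$q_stat, 1.0, tolerance = 1e-12)
  expect_equal(het$i2, 0)

  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    het <- heterogeneity(make_es(rnorm(k, 0, 0.5), runif(k, 0.01, 0.2)))
    expect_gte(het$q_stat, 0)
    expect_gte(het$i2, 0)
    expect_lt(het$i2, 100)
  }
})

test_that("DL and REML agree exactly when Q <= k - 1 (both truncate to zero)", {
  es <- make_es(c(0.10, 0.12, 0.11), rep(0.05, 3))
  dl <- pool_random_effects(es, tau2_method = "DL")
  reml <- pool_random_effects(es, tau2_method = "REML")
  expect_lte(dl$q_stat, 2)
  expect_equal(dl$tau2, 0)
  expect_equal(reml$tau2, 0)
  expect_equal(dl$pooled, reml$pooled, tolerance = 1e-12)
})

test_that("pooled estimate respects convexity and weight structure", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:15, 1)
    es <- make_es(rnorm(k, 0, 0.4), runif(k, 0.01, 0.3))
    res <- pool_random_effects(es, tau2_method = "DL")
    expect_gte(res$pooled, min(es$value) - 1e-12)
    expect_lte(res$pooled, max(es$value) + 1e-12)
    expect_true(res$ci_low <= res$pooled && res$pooled <= res$ci_high)
  }

  # tau2 = 0 and equal variances -> arithmetic mean
  es <- make_es(c(0.1, 0.11, 0.12, 0.13), rep(0.2, 4))
  res <- pool_random_effects(es, tau2_method = "DL")
  expect_equal(res$tau2, 0)
  expect_equal(res$pooled, mean(es$value), tolerance = 1e-12)

  # adding a finite-variance effect increases total weight at fixed tau2
  es5 <- dplyr::bind_rows(es, make_es(0.12, 0.5))
  res5 <- pool_random_effects(es5, tau2_method = "DL")
  expect_equal(res5$tau2, 0)
  expect_lt(res5$se, res$se)
})

test_that("pooling preconditions are enforced", {
  expect_error(pool_random_effects(make_es(0.5, 0.1)),
    class = "sitemeta_pooling_error"
  )
  expect_error(pool_random_effects(make_es(c(0.5, 0.1), c(0.1, -0.2))),
    class = "sitemeta_domain_error"
  )
  expect_error(
    pool_random_effects(
      make_es(c(0.5, 0.1), c(0.1, 0.2), metric = c("cohens_d", "pearson_r"))
    ),
    class = "sitemeta_domain_error"
  )
})

test_that("correlations pool on the raw and Fisher-z scales consistently", {
  es <- make_es(
    c(0.10, 0.25, 0.18), (1 - c(0.10, 0.25, 0.18)^2)^2 / (60 - 3 - 1),
    metric = "pearson_r", n = c(64, 64, 64), n_partialled = c(3, 3, 3)
  )
  raw <- pool_random_effects(es)
  fz <- pool_random_effects(es, r_scale = "fisher_z")
  expect_lt(abs(raw$pooled - fz$pooled), 0.01) # near-equal for small r
  expect_true(abs(fz$pooled) < 1)
  expect_true(fz$ci_low >= -1 && fz$ci_high <= 1)
})

test_that("meta-regression recovers a known moderator slope and matches the reference", {
  set.seed(21)
  k <- 15
  x <- runif(k, 0, 25)
  v <- runif(k, 0.01, 0.05)
  es <- make_es(0.1 + 0.02 * x + rnorm(k, 0, sqrt(v + 0.02^2)), v)
  fit <- meta_regress(es, x, moderator_name = "pct_users")
  expect_lt(abs(fit$beta - 0.02), 3 * fit$se_beta)

  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = es$value, vi = es$variance, mods = ~x, method = "REML")
  expect_equal(fit$beta, unname(ref$beta[2]), tolerance = 1e-5)
  expect_equal(fit$se_beta, unname(ref$se[2]), tolerance = 1e-5)
  expect_equal(fit$residual_tau2, unname(ref$tau2), tolerance = 1e-5)
})

test_that("meta-regression slope estimates are unbiased over repeated consortia", {
  set.seed(31)
  reps <- 200
  beta_hat <- numeric(reps)
  for (i in seq_len(reps)) {
    k <- 15
    x <- runif(k, 0, 25)
    v <- runif(k, 0.01, 0.05)
    es <- make_es(0.1 + 0.02 * x + rnorm(k, 0, sqrt(v + 0.01)), v)
    beta_hat[i] <- meta_regress(es, x)$beta
  }
  mc_se <- sd(beta_hat) / sqrt(reps)
  expect_lt(abs(mean(beta_hat) - 0.02), 3 * mc_se)

  # null moderator: estimates center at zero
  set.seed(32)
  beta_null <- replicate(200, {
    k <- 10
    v <- runif(k, 0.01, 0.05)
    es <- make_es(rnorm(k, 0.1, sqrt(v + 0.01)), v)
    meta_regress(es, runif(k, 0, 25))$beta
  })
  expect_lt(abs(mean(beta_null)), 3 * sd(beta_null) / sqrt(200))
})

test_that("meta-regression estimability preconditions", {
  es <- make_es(c(0.1, 0.2), c(0.05, 0.05))
  expect_error(meta_regress(es, c(1, 2)),
    class = "sitemeta_estimability_error"
  )
  es3 <- make_es(c(0.1, 0.2, 0.3), rep(0.05, 3))
  expect_error(meta_regress(es3, c(2, 2, 2)),
    class = "sitemeta_collinearity_error"
  )
})

test_that("compare_groups is pool_random_effects on the contrast effects", {
  es <- make_es(c(0.05, 0.15, 0.2, -0.1), runif(4, 0.02, 0.06))
  a <- compare_groups(es, tau2_method = "DL")
  b <- pool_random_effects(es, tau2_method = "DL")
  expect_equal(a$pooled, b$pooled)
  expect_equal(a$se, b$se)
  expect_equal(a$p_value, b$p_value)
})

test_that("random-effects CI attains nominal coverage over simulated consortia", {
  set.seed(51)
  reps <- 600
  delta <- -0.15
  tau <- 0.05
  covered <- logical(reps)
  for (i in seq_len(reps)) {
    k <- 15
    v <- runif(k, 0.02, 0.06)
    d <- rnorm(k, delta, tau) + rnorm(k, 0, sqrt(v))
    res <- pool_random_effects(make_es(d, v), tau2_method = "REML")
    covered[i] <- res$ci_low <= delta && delta <= res$ci_high
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
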