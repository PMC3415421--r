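test_that("null model returns textbook Pearson residuals", {
  # balanced intercept-only fit: probabilities 1/2, residuals +/-1
  y <- rep(c(1L, 0L), each = 50)
  nm <- fit_null(y)
  expect_equal(unname(nm$fitted_probs), rep(0.5, 100), tolerance = 1e-8)
  expect_equal(unname(nm$residuals), rep(c(1, -1), each = 50),
               tolerance = 1e-8)
  # 8 cases / 2 controls: mu = 0.8, case residual 0.2/sqrt(0.16) = 0.5
  nm2 <- fit_null(c(rep(1L, 8), rep(0L, 2)))
  expect_equal(unname(nm2$residuals[1]), 0.5, tolerance = 1e-8)
})

test_that("null model rejects degenerate inputs", {
  expect_error(fit_null(rep(1L, 10)), "both")
  y <- rep(c(1L, 0L), each = 20)
  expect_error(fit_null(y, covariates = y), "separat")
})

test_that("TH statistic sums squared centred values over carriers", {
  expect_equal(th_statistic(c(1, -1, 2, -2), 1:3), 6)   # mean already 0
  expect_equal(th_statistic(rep(3.7, 10), c(2, 5, 9)), 0)
  set.seed(431)
  x <- rnorm(30); idx <- sample(30, 7)
  expect_equal(th_statistic(x, idx), th_statistic(-x, idx))
})

test_that("TH resampling p-value matches subset enumeration on a toy sample", {
  y <- c(1L, 0L, 1L, 0L, 1L, 0L)
  cov <- c(0.5, -0.2, 1.1, 0.3, -0.7, 0.4)
  G <- c(1L, 1L, 0L, 0L, 0L, 0L)
  nm <- fit_null(y, cov)
  obs <- th_statistic(nm$residuals, which(G == 1L))
  p_exact <- th_enumeration_p(nm$residuals, m = 2, obs = obs)
  set.seed(432)
  B <- 1e4
  p_hat <- th_test(y, cov, G, n_resamples = B)$p_value
  expect_lt(abs(p_hat - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / B) + 2 / B)
})

test_that("degenerate carrier sets yield p = 1 with a flag", {
  y <- rep(c(1L, 0L), 20)
  r0 <- th_test(y, NULL, rep(0L, 40), n_resamples = 100)
  expect_identical(r0$p_value, 1)
  expect_true(r0$degenerate)
  r1 <- th_test(y, NULL, rep(1L, 40), n_resamples = 100)
  expect_identical(r1$p_value, 1)
  # balanced sample without informative covariates: residuals all +/- 1,
  # every resample reproduces the observed statistic exactly
  set.seed(433)
  r2 <- th_test(y, NULL, rep(c(1L, rep(0L, 7)), 5), n_resamples = 200)
  expect_identical(r2$p_value, 1)
})

test_that("TH p-values are uniform under the null with a covariate", {
  set.seed(434)
  cfg <- sim_config(n_cases = 100, n_controls = 100, delta = 0, rsq = 0.15)
  pv <- vapply(1:300, function(i) {
    coh <- simulate_cohort(cfg)
    th_test(coh$y, coh$covariate, coh$carriage, n_resamples = 200)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif")$p.value), 0.001)
})
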