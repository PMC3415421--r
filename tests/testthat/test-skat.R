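test_that("score orthogonal to the phenotype gives a null statistic", {
  g <- matrix(c(1, 1, 0, 0), ncol = 1)
  y <- c(1L, 0L, 1L, 0L)
  r <- skat_test(y, g, weights = "unweighted", mode = "asymptotic")
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-6)
})

test_that("beta(1,25) MAF weights follow the closed-form density", {
  expect_equal(rvth:::.beta_maf_weight(0.005), 25 * 0.995^24,
               tolerance = 1e-10)
  expect_equal(rvth:::.beta_maf_weight(0.005), 22.17, tolerance = 1e-3)
  # rarer variants are up-weighted
  expect_gt(rvth:::.beta_maf_weight(0.001), rvth:::.beta_maf_weight(0.01))
})

test_that("mixture-of-chi-square tail matches a Monte-Carlo oracle", {
  lambda <- c(2, 1, 0.5)
  set.seed(461)
  mc <- colSums(lambda * matrix(rchisq(3 * 2e5, df = 1), 3))
  for (q in c(2, 6, 12)) {
    p_mc <- mean(mc > q)
    se <- sqrt(p_mc * (1 - p_mc) / length(mc))
    expect_lt(abs(rvth:::pchisq_mixture(q, lambda) - p_mc), 3 * se)
  }
  # moment-matching fallback stays close to the inversion
  expect_lt(abs(rvth:::.liu_tail(6, lambda) -
                  rvth:::pchisq_mixture(6, lambda)), 0.02)
})

test_that("asymptotic and bootstrap p agree when scores are near-normal", {
  # large per-variant minor-allele counts: the mixture asymptotics hold,
  # so the parametric bootstrap must reproduce them within MC noise
  set.seed(462)
  B <- 5000
  for (i in 1:8) {
    n <- 600
    G <- matrix(rbinom(n * 8, 2, 0.25), n, 8)
    C <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.4 * C))
    pa <- skat_test(y, G, C, weights = "unweighted",
                    mode = "asymptotic")$p_value
    pb <- skat_test(y, G, C, weights = "unweighted", mode = "bootstrap",
                    n_boot = B)$p_value
    expect_lt(abs(pa - pb), 3 * sqrt(pb * (1 - pb) / B) + 2 / B)
  }
})

test_that("monomorphic genotype matrices are flagged degenerate", {
  y <- rep(c(1L, 0L), 10)
  r <- skat_test(y, matrix(0L, 20, 3))
  expect_identical(r$p_value, 1)
  expect_true(r$degenerate)
})
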