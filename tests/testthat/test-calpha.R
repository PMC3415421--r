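test_that("statistic and variance match exact binomial enumeration", {
  # one variant, both copies in cases, p0 = 1/2
  s <- calpha_statistic(2, 2, 0.5)
  expect_equal(s$T, 0.5, tolerance = 1e-12)
  expect_equal(s$c, 0.25, tolerance = 1e-12)
  expect_equal(s$T / sqrt(s$c), 1, tolerance = 1e-12)
  # two such variants: T = 1, c = 0.5, one-sided normal tail
  s2 <- calpha_statistic(c(2, 2), c(2, 2), 0.5)
  expect_equal(s2$T, 1, tolerance = 1e-12)
  expect_equal(s2$c, 0.5, tolerance = 1e-12)
  expect_equal(pnorm(s2$T / sqrt(s2$c), lower.tail = FALSE), 0.0786496,
               tolerance = 1e-6)
})

test_that("singletons contribute nothing at a balanced case fraction", {
  s <- calpha_statistic(c(1, 0, 1), c(1, 1, 1), 0.5)
  expect_equal(s$T, 0, tolerance = 1e-12)
  expect_equal(s$c, 0, tolerance = 1e-12)
  # through the test interface: degenerate, p = 1
  geno <- diag(1L, 4)
  y <- c(1L, 0L, 1L, 0L)
  r <- calpha_test(geno, y, mode = "asymptotic")
  expect_identical(r$p_value, 1)
  expect_true(r$degenerate)
})

test_that("T and c are additive over variants", {
  set.seed(451)
  nj <- sample(1:6, 5, replace = TRUE)
  yj <- vapply(nj, function(n) sample(0:n, 1), integer(1))
  one <- calpha_statistic(yj, nj, 0.3)
  two <- calpha_statistic(c(yj, yj), c(nj, nj), 0.3)
  expect_equal(two$T, 2 * one$T, tolerance = 1e-12)
  expect_equal(two$c, 2 * one$c, tolerance = 1e-12)
})

test_that("permutation p-value matches full label enumeration on 6 subjects", {
  geno <- matrix(0L, 6, 2)
  geno[1, 1] <- 1L; geno[2, 1] <- 1L; geno[3, 2] <- 1L; geno[4, 2] <- 1L
  y <- c(1L, 1L, 0L, 0L, 1L, 0L)
  obs <- calpha_statistic(as.vector(crossprod(geno, y)), colSums(geno),
                          mean(y))$T
  p_exact <- calpha_enumeration_p(geno, y, obs)
  set.seed(452)
  B <- 1e4
  p_hat <- calpha_test(geno, y, mode = "permutation",
                       n_permutations = B)$p_value
  expect_lt(abs(p_hat - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / B) + 2 / B)
})

test_that("asymptotic p is invariant to subject and variant reordering", {
  coh <- quick_cohort(453, n = 100, delta = 0.5, zeta = 0.5)
  p1 <- calpha_test(coh$genotypes, coh$y)$p_value
  sidx <- sample(nrow(coh$genotypes))
  vidx <- sample(ncol(coh$genotypes))
  p2 <- calpha_test(coh$genotypes[sidx, vidx], coh$y[sidx])$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})
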