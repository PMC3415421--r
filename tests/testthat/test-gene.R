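test_that("carriage target follows the 1% per 500 bp calibration", {
  set.seed(411)
  expect_equal(build_gene(500)$target_carriage, 0.01)
  expect_equal(build_gene(4057)$target_carriage, 0.01 * 4057 / 500)
})

test_that("accumulation stops at the closest achievable carriage", {
  set.seed(412)
  for (i in 1:100) {
    g <- build_gene(sample(c(361, 1209, 4057), 1))
    expect_gte(length(g$maf), 1)
    achieved <- 1 - prod(1 - g$maf)
    expect_equal(achieved, g$carriage, tolerance = 1e-12)
    # keeping the last variant was the closer choice
    without_last <- 1 - prod(1 - g$maf[-length(g$maf)])
    expect_lte(abs(achieved - g$target_carriage),
               abs(without_last - g$target_carriage))
  }
})

test_that("a single overshooting draw that beats the empty gene is kept alone", {
  # window forced to [0.004, 0.005): with target 0.004 the first draw is
  # within 0.001 of target (closer than 0), any second draw overshoots
  wp <- wright_params(maf_lower = 0.004, maf_upper = 0.005)
  set.seed(413)
  for (i in 1:20) {
    g <- build_gene(200, params = wp)
    expect_identical(length(g$maf), 1L)
    expect_lt(abs(g$carriage - g$target_carriage),
              g$target_carriage)
  }
})

test_that("damage classes and signs follow their marginal distributions", {
  set.seed(414)
  genes <- lapply(1:250, function(i) build_gene(4057, zeta = 0.8))
  cls <- unlist(lapply(genes, `[[`, "damage_class"))
  sgn <- unlist(lapply(genes, `[[`, "sign"))
  n <- length(cls)
  expect_gt(n, 1e4)
  probs <- c(0.26, 0.16, 0.36, 0.22)
  emp <- tabulate(cls + 1L, 4) / n
  expect_true(all(abs(emp - probs) < 3 * sqrt(probs * (1 - probs) / n)))
  expect_lt(abs(mean(sgn == 1) - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})
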