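tiny_spec <- function(...) {
  grid_spec(deltas = 0.6, zetas = 1, rsqs = 0.15, cds_lengths = 361,
            n_sims_power = 12L, n_sims_size = 12L, alpha = 0.05,
            methods = c("RCS-C", "CA-P"), n_resamples = 100L, ...)
}
tiny_template <- function() sim_config(n_cases = 60, n_controls = 60)

test_that("grid runs are bit-identical under the same master seed", {
  r1 <- suppressWarnings(estimate_power(tiny_spec(), tiny_template(), master_seed = 481))
  r2 <- suppressWarnings(estimate_power(tiny_spec(), tiny_template(), master_seed = 481))
  expect_identical(r1, r2)
  r3 <- suppressWarnings(estimate_size(tiny_spec(), tiny_template(), master_seed = 482))
  expect_identical(unique(r3$delta), 0)
  expect_identical(r3, suppressWarnings(estimate_size(tiny_spec(), tiny_template(),
                                                      master_seed = 482)))
})

test_that("grid results carry coherent estimates and Monte-Carlo errors", {
  spec <- tiny_spec()
  res <- suppressWarnings(estimate_power(spec, tiny_template(), master_seed = 483,
                                         keep_pvalues = TRUE))
  expect_identical(nrow(res), length(spec$methods))
  expect_true(all(res$estimate >= 0 & res$estimate <= 1))
  expect_equal(res$mc_se, sqrt(res$estimate * (1 - res$estimate) / res$n_sims))
  expect_equal(res$relative_size, res$estimate / spec$alpha)
  pv <- attr(res, "pvalues")[[1]]
  expect_identical(dim(pv), c(12L, 2L))
  expect_true(all(pv >= 0 & pv <= 1, na.rm = TRUE))
})

test_that("summaries round-trip through CSV", {
  res <- suppressWarnings(estimate_power(tiny_spec(), tiny_template(), master_seed = 484))
  path <- file.path(withr::local_tempdir(), "grid.csv")
  summarize_grid(res, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), nrow(res))
  expect_equal(back$estimate, res$estimate)
  expect_equal(back$relative_size, res$relative_size)
})
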