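#' Run a panel of rare-variant association tests on one gene
#'
#' Applies any subset of the implemented methods to a genotype matrix,
#' binary phenotype and optional covariates, sharing the null logistic
#' fit where possible. Method tags: \code{"TH"} (trend-and-heterogeneity,
#' resampling), \code{"RCS"} / \code{"RCS-C"} (logistic regression on
#' carriage, without/with covariates), \code{"CA"} / \code{"CA-P"}
#' (C-alpha, asymptotic / permutation), \code{"SK"} / \code{"SK-R"}
#' (SKAT-type score test, asymptotic / parametric bootstrap).
#'
#' @param y binary 0/1 phenotype.
#' @param genotypes subjects x variants matrix of allele copies.
#' @param covariates optional covariate matrix/vector (used by TH, RCS-C,
#'   SK, SK-R).
#' @param methods character vector of method tags.
#' @param n_resamples resampling/permutation/bootstrap replicates for the
#'   Monte-Carlo methods.
#' @param skat_weights passed to [skat_test()].
#' @return a data frame with one row per method (columns \code{method},
#'   \code{statistic}, \code{p_value}, \code{mode}, \code{n_resamples},
#'   \code{degenerate}).
#' @export
#' @examples
#' set.seed(42)
#' coh <- simulate_cohort(sim_config(n_cases = 100, n_controls = 100,
#'                                   rsq = 0.15, delta = 0.8, zeta = 1))
#' run_rv_tests(coh$y, coh$genotypes, coh$covariate,
#'              methods = c("RCS-C", "CA-P", "TH"), n_resamples = 500)
run_rv_tests <- function(y, genotypes, covariates = NULL,
                         methods = c("TH", "RCS-C", "CA", "CA-P", "SK-R"),
                         n_resamples = 10000L,
                         skat_weights = "beta") {
  known <- c("TH", "RCS", "RCS-C", "CA", "CA-P", "SK", "SK-R")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method tag(s): ", paste(bad, collapse = ", "))
  genotypes <- as.matrix(genotypes)
  G <- as.integer(rowSums(genotypes) > 0)
  res <- lapply(methods, function(m) {
    r <- switch(m,
      "TH"    = th_test(y, covariates, G, n_resamples = n_resamples),
      "RCS"   = rcs_test(y, G),
      "RCS-C" = rcs_test(y, G, covariates),
      "CA"    = calpha_test(genotypes, y, mode = "asymptotic"),
      "CA-P"  = calpha_test(genotypes, y, mode = "permutation",
                            n_permutations = n_resamples),
      "SK"    = skat_test(y, genotypes, covariates, weights = skat_weights,
                          mode = "asymptotic"),
      "SK-R"  = skat_test(y, genotypes, covariates, weights = skat_weights,
                          mode = "bootstrap", n_boot = n_resamples))
    as.data.frame(r)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write test results to CSV
#'
#' @param results data frame as returned by [run_rv_tests()].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
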