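#' Logistic regression on carriage status (RCS / RCS-C)
#'
#' Collapsing test: likelihood-ratio comparison of the logistic model
#' \code{y ~ intercept [+ covariates] + G} against the nested model
#' without the carriage indicator \code{G} (1 df). With covariates this is
#' the RCS-C method; without, RCS.
#'
#' @param y binary 0/1 phenotype.
#' @param G binary carriage vector.
#' @param covariates optional covariate matrix/vector (their presence
#'   switches the method tag to \code{"RCS-C"}).
#' @return a [test_result()] with the LRT statistic and its chi-square(1)
#'   upper-tail p-value.
#' @export
rcs_test <- function(y, G, covariates = NULL) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("y must contain both cases and controls")
  G <- as.numeric(G > 0)
  n <- length(y)
  stopifnot(length(G) == n)
  tag <- if (is.null(covariates)) "RCS" else "RCS-C"
  if (length(unique(G)) < 2L)
    return(test_result(tag, 0, 1, "asymptotic", degenerate = TRUE))
  X0 <- cbind(rep(1, n))
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  X1 <- cbind(X0, G = G)
  ctl <- list(maxit = 50)
  f0 <- suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial(),
                                        control = ctl))
  f1 <- suppressWarnings(stats::glm.fit(X1, y, family = stats::binomial(),
                                        control = ctl))
  sep <- !f1$converged || max(abs(f1$coefficients), na.rm = TRUE) > 20
  if (sep)
    warning("separation or non-convergence in the carriage model; ",
            "LRT taken at the iteration cap")
  lrt <- max(f0$deviance - f1$deviance, 0)
  test_result(tag, lrt, stats::pchisq(lrt, df = 1, lower.tail = FALSE),
              "asymptotic", degenerate = sep)
}
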