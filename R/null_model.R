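#' Fit the null logistic model and extract Pearson residuals
#'
#' Maximum-likelihood logistic regression of the binary trait on an
#' intercept and the supplied covariates (intercept-only when none). The
#' Pearson residual \eqn{(y_i - \hat\mu_i) / \sqrt{\hat\mu_i (1 -
#' \hat\mu_i)}} is the quantitative pseudo-trait used by the TH test and
#' the fitted probabilities feed the SKAT-type score statistic and its
#' parametric bootstrap.
#'
#' @param y binary 0/1 response containing both classes.
#' @param covariates optional numeric matrix (or vector) of covariates.
#' @return list of class \code{rv_null_model} with \code{fitted_probs},
#'   \code{residuals} (Pearson), \code{X} (design matrix incl. intercept)
#'   and the \code{glm} \code{fit}.
#' @export
fit_null <- function(y, covariates = NULL) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y must contain both cases and controls")
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 50)))
  mu <- fit$fitted.values
  if (!fit$converged)
    stop("null logistic fit did not converge within 50 iterations")
  ## separation drives coefficients towards +/- infinity; genuinely strong
  ## covariates stay at moderate magnitudes
  if (max(abs(fit$coefficients), na.rm = TRUE) > 20)
    stop("null logistic fit is separated (diverging coefficients)")
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  structure(list(fitted_probs = mu,
                 residuals = (y - mu) / sqrt(mu * (1 - mu)),
                 X = X, fit = fit),
            class = "rv_null_model")
}
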