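## beta(1,25)-density MAF weight, the standard up-weighting of rarer
## variants in the weighted linear kernel
.beta_maf_weight <- function(maf) stats::dbeta(maf, 1, 25)

#' SKAT-type variance-component score test
#'
#' Kernel score test of the binary trait against all variants in the gene
#' jointly. After fitting the null logistic model of \code{y} on the
#' covariates (fitted probabilities \eqn{\hat\mu}), the score statistic is
#' \deqn{Q = (y - \hat\mu)^\top G W G^\top (y - \hat\mu),}
#' with \eqn{W} diagonal holding the squared beta(1,25)-density weights of
#' each variant's sample MAF (linear weighted kernel; identity for
#' \code{weights = "unweighted"}).
#'
#' Asymptotic p-values come from the tail of \eqn{\sum_k \lambda_k
#' \chi^2_1}, where \eqn{\lambda_k} are the eigenvalues of
#' \eqn{W^{1/2} G^\top P G W^{1/2}} with
#' \eqn{P = V - V X (X^\top V X)^{-1} X^\top V},
#' \eqn{V = diag(\hat\mu(1-\hat\mu))}: the projection accounts for the
#' estimated null coefficients. The parametric bootstrap simulates
#' \eqn{y^*_i \sim Bernoulli(\hat\mu_i)} and recomputes \eqn{Q} with the
#' null model re-estimated by a one-step score update (the bootstrap
#' residuals are projected as \eqn{z^* - V X (X^\top V X)^{-1} X^\top
#' z^*}, the first-order equivalent of refitting the logistic null),
#' giving \eqn{p = (1 + \#\{Q^* \ge Q_{obs}\}) / (B + 1)}. Because only
#' carrier rows of \eqn{G} are non-zero, carrier subjects are simulated
#' exactly and the non-carrier contribution to the low-dimensional
#' nuisance score \eqn{X^\top z^*} — a sum over all remaining subjects —
#' is drawn from its (exact-covariance) normal limit.
#'
#' @param y binary 0/1 phenotype.
#' @param genotypes subjects x variants matrix of allele copies.
#' @param covariates optional covariate matrix/vector.
#' @param weights \code{"beta"} (beta(1,25) MAF weights, the default) or
#'   \code{"unweighted"}.
#' @param mode \code{"asymptotic"} or \code{"bootstrap"}.
#' @param n_boot bootstrap replicate count \eqn{B}.
#' @return a [test_result()] with method tag \code{"SK"} or \code{"SK-R"}.
#' @export
skat_test <- function(y, genotypes, covariates = NULL,
                      weights = c("beta", "unweighted"),
                      mode = c("asymptotic", "bootstrap"),
                      n_boot = 10000L) {
  weights <- match.arg(weights)
  mode <- match.arg(mode)
  y <- as.integer(y)
  genotypes <- as.matrix(genotypes)
  n <- length(y)
  stopifnot(nrow(genotypes) == n)
  tag <- if (mode == "asymptotic") "SK" else "SK-R"
  poly <- which(colSums(genotypes) > 0 & colSums(genotypes) < 2 * n)
  if (length(poly) == 0L)
    return(test_result(tag, 0, 1, mode, degenerate = TRUE))
  G <- genotypes[, poly, drop = FALSE]
  maf <- colSums(G) / (2 * n)
  maf <- pmin(maf, 1 - maf)
  w <- if (weights == "beta") .beta_maf_weight(maf) else rep(1, ncol(G))
  nm <- fit_null(y, covariates)
  mu <- nm$fitted_probs
  z <- y - mu
  Gw <- sweep(G, 2, w, `*`)            # columns scaled by w (sqrt of W = w^2)
  score <- as.vector(crossprod(Gw, z))
  q_obs <- sum(score^2)
  v <- mu * (1 - mu)
  X <- nm$X
  XvX <- crossprod(X * sqrt(v))
  GvX <- crossprod(Gw * v, X)               # W^.5 G' V X
  if (mode == "bootstrap") {
    B <- as.integer(n_boot)
    stopifnot(B >= 1)
    carriers <- which(rowSums(G) > 0)
    Gc <- Gw[carriers, , drop = FALSE]
    mu_c <- mu[carriers]
    Xc <- X[carriers, , drop = FALSE]
    U <- GvX %*% solve(XvX)                 # p x k projection coefficients
    ## exact covariance of the non-carrier part of X' z*
    Snc <- crossprod(X[-carriers, , drop = FALSE] *
                       sqrt(v[-carriers]))
    Lnc <- if (nrow(X) > length(carriers)) chol(Snc) else
      matrix(0, ncol(X), ncol(X))
    nc <- length(carriers)
    k <- ncol(X)
    q_star <- numeric(B)
    block <- 2000L
    for (b0 in seq(1L, B, by = block)) {
      bb <- min(block, B - b0 + 1L)
      Zs <- matrix(stats::rbinom(nc * bb, 1L, mu_c) - mu_c, nc, bb)
      SC <- crossprod(Gc, Zs)                               # p x bb
      XZ <- crossprod(Xc, Zs) +
        t(Lnc) %*% matrix(stats::rnorm(k * bb), k, bb)      # k x bb
      q_star[b0:(b0 + bb - 1L)] <- colSums((SC - U %*% XZ)^2)
    }
    p <- (1 + sum(q_star >= q_obs - 1e-12)) / (B + 1)
    return(test_result("SK-R", q_obs, p, "bootstrap", B))
  }
  ## asymptotic: eigenvalues of W^{1/2} G' (V - VX(X'VX)^-1 X'V) G W^{1/2}
  GvG <- crossprod(Gw * sqrt(v))            # W^.5 G' V G W^.5
  A <- GvG - GvX %*% solve(XvX, t(GvX))
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lambda <- ev[ev > max(ev, 0) * 1e-10]
  if (length(lambda) == 0L)
    return(test_result("SK", q_obs, 1, "asymptotic", degenerate = TRUE))
  test_result("SK", q_obs, pchisq_mixture(q_obs, lambda), "asymptotic")
}
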