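## Upper-tail probability of a positively weighted sum of independent
## 1-df chi-squares, P(sum_k lambda_k X_k > q).
##
## Primary route: numerical inversion of the characteristic function
## (Imhof's integral) via adaptive quadrature; fallback: Liu-Tang-Zhang
## four-moment matching to a non-central chi-square, used when the
## inversion fails or leaves [0, 1].

.imhof_tail <- function(q, lambda, rel_tol = 1e-8) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- try(stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                              abs.tol = 1e-10, subdivisions = 10000L,
                              stop.on.error = FALSE),
             silent = TRUE)
  if (inherits(val, "try-error") || !is.finite(val$value) ||
      val$abs.error > 1e-4)
    return(NA_real_)
  0.5 + val$value / pi
}

.liu_tail <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    a <- 1 / s1
    ncp <- 0
    df <- c2^3 / c3^2
  }
  mu_x <- df + ncp
  sigma_x <- sqrt(2) * a
  t_star <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(t_star * sigma_x + mu_x, df = df, ncp = ncp,
                lower.tail = FALSE)
}

#' Tail probability of a mixture of chi-squares
#'
#' \eqn{P(\sum_k \lambda_k \chi^2_{1,k} > q)} for positive weights, by
#' characteristic-function inversion with a moment-matching fallback.
#'
#' @param q quantile.
#' @param lambda positive mixture weights.
#' @return upper-tail probability in [0, 1].
#' @keywords internal
pchisq_mixture <- function(q, lambda) {
  lambda <- lambda[lambda > max(lambda) * 1e-10]
  if (length(lambda) == 0 || q <= 0) return(1)
  if (length(lambda) == 1)
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  p <- .imhof_tail(q, lambda)
  if (is.na(p) || p < 0 || p > 1) p <- .liu_tail(q, lambda)
  min(max(p, 0), 1)
}
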