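#' Hyper-parameters for Wright's stationary allele-frequency distribution
#'
#' Rare-variant site frequencies are drawn from Wright's stationary
#' distribution \deqn{\psi(p) \propto p^{\beta_1 - 1} (1 - p)^{\beta_2 - 1}
#' e^{\sigma (1 - p)},} truncated to the rare-variant window
#' \eqn{[maf\_lower, maf\_upper)}. The shape parameters are themselves drawn
#' per variant from hyper-priors: \eqn{\beta_1 \sim U(beta1\_range)},
#' \eqn{\beta_2 \sim U(beta2\_range)}, and the (scaled) selection parameter
#' \eqn{\sigma} is 0 with probability \code{sigma_zero_prob} and otherwise
#' uniform on \code{sigma_range}.
#'
#' With \code{beta1_range} well below 1 the density behaves like
#' \eqn{p^{-1}} near zero, concentrating mass at the rarest frequencies, as
#' expected for deleterious coding variation.
#'
#' @param beta1_range length-2 numeric, uniform range for \eqn{\beta_1}.
#' @param beta2_range length-2 numeric, uniform range for \eqn{\beta_2}.
#' @param sigma_zero_prob probability that \eqn{\sigma = 0}.
#' @param sigma_range length-2 numeric, uniform range for \eqn{\sigma} when
#'   it is non-zero.
#' @param maf_upper exclusive upper bound of the minor-allele-frequency
#'   window; the rare-variant definition (default 0.005, i.e. MAF < 0.5\%).
#' @param maf_lower inclusive lower bound (grid floor, default 1/20000).
#' @param grid_points number of equally spaced grid points used to
#'   discretise the truncated density for sampling.
#' @return an object of class \code{wright_params}.
#' @seealso [sample_wright_frequency()], [build_gene()]
#' @export
#' @examples
#' wp <- wright_params()
#' summary(sample_wright_frequency(1000, wp))
wright_params <- function(beta1_range = c(0.001, 0.003),
                          beta2_range = c(1, 5),
                          sigma_zero_prob = 0.5,
                          sigma_range = c(0, 20),
                          maf_upper = 0.005,
                          maf_lower = 1 / 20000,
                          grid_points = 512L) {
  stopifnot(length(beta1_range) == 2, length(beta2_range) == 2,
            length(sigma_range) == 2)
  if (beta1_range[1] > beta1_range[2] || beta2_range[1] > beta2_range[2] ||
      sigma_range[1] > sigma_range[2])
    stop("parameter ranges must be ordered low <= high")
  if (any(c(beta1_range, beta2_range) <= 0))
    stop("beta1_range and beta2_range must be positive")
  if (sigma_zero_prob < 0 || sigma_zero_prob > 1)
    stop("sigma_zero_prob must be a probability")
  if (!(maf_lower > 0 && maf_lower < maf_upper && maf_upper <= 0.5))
    stop("need 0 < maf_lower < maf_upper <= 0.5")
  grid_points <- as.integer(grid_points)
  if (grid_points < 2) stop("grid_points must be >= 2")
  structure(list(beta1_range = beta1_range, beta2_range = beta2_range,
                 sigma_zero_prob = sigma_zero_prob, sigma_range = sigma_range,
                 maf_upper = maf_upper, maf_lower = maf_lower,
                 grid_points = grid_points),
            class = "wright_params")
}

#' @export
print.wright_params <- function(x, ...) {
  cat("Wright's distribution hyper-parameters\n")
  cat(sprintf("  beta1 ~ U(%g, %g), beta2 ~ U(%g, %g)\n",
              x$beta1_range[1], x$beta1_range[2],
              x$beta2_range[1], x$beta2_range[2]))
  cat(sprintf("  sigma = 0 w.p. %g, else U(%g, %g)\n",
              x$sigma_zero_prob, x$sigma_range[1], x$sigma_range[2]))
  cat(sprintf("  MAF window [%g, %g), %d grid points\n",
              x$maf_lower, x$maf_upper, x$grid_points))
  invisible(x)
}

## log of the (unnormalised) Wright density on a frequency grid
.wright_log_density <- function(p, beta1, beta2, sigma) {
  (beta1 - 1) * log(p) + (beta2 - 1) * log1p(-p) + sigma * (1 - p)
}

#' Draw rare-variant minor-allele frequencies from Wright's distribution
#'
#' For each draw a fresh (\eqn{\beta_1}, \eqn{\beta_2}, \eqn{\sigma}) triple
#' is taken from the hyper-priors in \code{params}, the truncated density is
#' evaluated on a uniform grid over \eqn{[maf\_lower, maf\_upper)}, and one
#' grid point is sampled with probability proportional to its density
#' (inverse-CDF sampling on the discretised density).
#'
#' @param n number of frequencies to draw.
#' @param params a [wright_params()] object.
#' @return numeric vector of length \code{n}, all values in
#'   \eqn{[maf\_lower, maf\_upper)}.
#' @export
sample_wright_frequency <- function(n, params = wright_params()) {
  stopifnot(inherits(params, "wright_params"), n >= 0)
  if (params$maf_lower >= params$maf_upper)
    stop("degenerate frequency grid: maf_lower >= maf_upper")
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  ## grid of cell midpoints so every sampled value is strictly below maf_upper
  k <- params$grid_points
  step <- (params$maf_upper - params$maf_lower) / k
  grid <- params$maf_lower + (seq_len(k) - 0.5) * step
  beta1 <- stats::runif(n, params$beta1_range[1], params$beta1_range[2])
  beta2 <- stats::runif(n, params$beta2_range[1], params$beta2_range[2])
  sigma <- ifelse(stats::runif(n) < params$sigma_zero_prob, 0,
                  stats::runif(n, params$sigma_range[1], params$sigma_range[2]))
  out <- numeric(n)
  for (i in seq_len(n)) {
    lw <- .wright_log_density(grid, beta1[i], beta2[i], sigma[i])
    w <- exp(lw - max(lw))
    out[i] <- grid[sample.int(k, 1L, prob = w)]
  }
  out
}
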