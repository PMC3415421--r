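#' Build a simulated gene model
#'
#' A gene is a set of independent rare-variant sites. Site frequencies are
#' drawn one at a time from Wright's distribution ([sample_wright_frequency()])
#' and accumulated until the expected probability that a subject carries at
#' least one rare variant, \eqn{1 - \prod_j (1 - q_j)}, is as close as
#' possible to the calibration target of 1\% carriage per 500 coding base
#' pairs, i.e. \code{target_carriage = 0.01 * cds_length / 500}. Each sampled
#' frequency \eqn{q_j} is used directly as the per-subject carriage
#' probability of site \eqn{j}; see the methods vignette for the rationale.
#'
#' The first drawn site is always kept (a gene has at least one variant).
#' Each subsequent candidate is kept if and only if including it moves the
#' accumulated carriage closer to the target; the first rejected candidate
#' ends the accumulation.
#'
#' Each site independently receives a deleteriousness class \eqn{D_t \in
#' \{0, 1, 2, 3\}} with probabilities \code{class_probs} (0 = benign, 3 =
#' very deleterious) and an effect sign, +1 (risk increasing) with
#' probability \code{zeta} and -1 otherwise. \code{zeta} = 1 is effect
#' homogeneity, 0.5 complete heterogeneity.
#'
#' @param cds_length coding-sequence length in base pairs (> 0).
#' @param class_probs length-4 probability vector for classes 0--3.
#' @param zeta probability that a site's effect is risk increasing.
#' @param params a [wright_params()] object.
#' @return an object of class \code{rv_gene}: a list with elements
#'   \code{cds_length}, \code{target_carriage}, \code{maf},
#'   \code{damage_class}, \code{sign} and \code{carriage} (the achieved
#'   expected carriage probability).
#' @export
#' @examples
#' set.seed(1)
#' g <- build_gene(1209)
#' g
build_gene <- function(cds_length,
                       class_probs = c(0.26, 0.16, 0.36, 0.22),
                       zeta = 0.5,
                       params = wright_params()) {
  stopifnot(length(cds_length) == 1, cds_length > 0,
            length(class_probs) == 4, all(class_probs >= 0),
            zeta >= 0, zeta <= 1)
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1")
  target <- 0.01 * cds_length / 500
  maf <- numeric(0)
  non_carriage <- 1        # prod_j (1 - q_j)
  repeat {
    q <- sample_wright_frequency(1L, params)
    cand <- 1 - non_carriage * (1 - q)
    if (length(maf) == 0L ||
        abs(cand - target) < abs((1 - non_carriage) - target)) {
      maf <- c(maf, q)
      non_carriage <- non_carriage * (1 - q)
    } else break
  }
  p <- length(maf)
  structure(list(
    cds_length = cds_length,
    target_carriage = target,
    maf = maf,
    damage_class = sample(0:3, p, replace = TRUE, prob = class_probs),
    sign = ifelse(stats::runif(p) < zeta, 1L, -1L),
    carriage = 1 - non_carriage
  ), class = "rv_gene")
}

#' @export
print.rv_gene <- function(x, ...) {
  cat(sprintf("Simulated gene: %d bp CDS, %d rare-variant sites\n",
              x$cds_length, length(x$maf)))
  cat(sprintf("  carriage probability %.4f (target %.4f)\n",
              x$carriage, x$target_carriage))
  cat(sprintf("  MAF range [%.3g, %.3g]; %d risk-increasing sites\n",
              min(x$maf), max(x$maf), sum(x$sign > 0)))
  invisible(x)
}
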