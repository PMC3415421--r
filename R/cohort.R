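#' Simulation configuration
#'
#' Bundles the design parameters of the liability-threshold case-control
#' simulator. A subject's latent trait is
#' \deqn{Z = \delta \, s \, d + \gamma C + \epsilon,}
#' where \eqn{s} and \eqn{d} come from the retained (most deleterious
#' carried) variant, \eqn{C \sim N(0,1)} is a covariate and
#' \eqn{\epsilon \sim N(0, 1 - \gamma^2)}, so the null latent trait is
#' standard normal. A subject is a case when \eqn{Z} exceeds the
#' \eqn{1 - K} quantile of the null latent distribution \eqn{N(0,1)}.
#'
#' \code{rsq} is the fraction of the variance of the observed binary
#' trait explained by the covariate (the default,
#' \code{rsq_scale = "binary"}). For a bivariate-normal (covariate,
#' liability) pair the squared correlation between \eqn{C} and the binary
#' indicator is exactly \eqn{\gamma^2 \phi(z_K)^2 / (K(1-K))} with
#' \eqn{z_K} the threshold, so
#' \deqn{\gamma = \sqrt{Rsq \; K(1-K)} \, / \, \phi(z_K).}
#' With \code{rsq_scale = "latent"}, \code{rsq} is instead the fraction of
#' latent (liability) variance, i.e. \eqn{\gamma = \sqrt{Rsq}}.
#'
#' Under \code{scenario = "linear"} the latent effect is proportional to
#' the damage class (\eqn{d = D_t}); under \code{scenario = "magnitude"}
#' every carried deleterious variant has the same magnitude
#' (\eqn{d = I[D_t > 0]}).
#'
#' @param n_cases,n_controls ascertained sample sizes.
#' @param prevalence population prevalence \eqn{K} of the binary trait.
#' @param rsq fraction of trait variance explained by the covariate, on
#'   the scale chosen by \code{rsq_scale} (see Details).
#' @param rsq_scale \code{"binary"} (observed-scale variance explained,
#'   the default) or \code{"latent"} (liability-scale).
#' @param delta effect size: latent-mean difference between adjacent damage
#'   classes, in latent standard deviations.
#' @param zeta probability that a variant is risk increasing (heterogeneity
#'   parameter; 1 = homogeneity, 0.5 = complete heterogeneity).
#' @param cds_length coding-sequence length in bp of the simulated gene.
#' @param scenario \code{"linear"} or \code{"magnitude"} (see Details).
#' @param class_probs marginal distribution of damage classes 0--3.
#' @param wright a [wright_params()] object.
#' @param seed optional integer seed applied by the simulation functions.
#' @param max_subjects cap on generated subjects during ascertainment;
#'   default \code{200 * (n_cases + n_controls) / min(K, 1 - K)}.
#' @return an object of class \code{rv_sim_config}.
#' @export
sim_config <- function(n_cases = 1000L, n_controls = 1000L,
                       prevalence = 0.1, rsq = 0, delta = 0, zeta = 0.5,
                       rsq_scale = c("binary", "latent"),
                       cds_length = 1209,
                       scenario = c("linear", "magnitude"),
                       class_probs = c(0.26, 0.16, 0.36, 0.22),
                       wright = wright_params(),
                       seed = NULL,
                       max_subjects = NULL) {
  scenario <- match.arg(scenario)
  rsq_scale <- match.arg(rsq_scale)
  stopifnot(n_cases >= 1, n_controls >= 1,
            prevalence > 0, prevalence < 1,
            rsq >= 0, rsq < 1, zeta >= 0, zeta <= 1,
            delta >= 0, cds_length > 0,
            length(class_probs) == 4, all(class_probs >= 0))
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  latent_rsq <- if (rsq_scale == "binary") {
    zk <- stats::qnorm(1 - prevalence)
    rsq * prevalence * (1 - prevalence) / stats::dnorm(zk)^2
  } else rsq
  if (latent_rsq >= 1)
    stop(sprintf(
      "rsq = %g on the %s scale implies a covariate coefficient >= 1 SD of liability (latent fraction %.3f); reduce rsq",
      rsq, rsq_scale, latent_rsq))
  if (is.null(max_subjects))
    max_subjects <- ceiling(200 * (n_cases + n_controls) /
                              min(prevalence, 1 - prevalence))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 prevalence = prevalence, rsq = rsq,
                 rsq_scale = rsq_scale, latent_rsq = latent_rsq,
                 delta = delta,
                 zeta = zeta, cds_length = cds_length, scenario = scenario,
                 class_probs = class_probs, wright = wright, seed = seed,
                 max_subjects = max_subjects),
            class = "rv_sim_config")
}

#' @export
print.rv_sim_config <- function(x, ...) {
  cat("Case-control simulation configuration\n")
  cat(sprintf("  %d cases / %d controls, prevalence K = %g\n",
              x$n_cases, x$n_controls, x$prevalence))
  cat(sprintf("  delta = %g, zeta = %g, Rsq = %g, scenario = %s\n",
              x$delta, x$zeta, x$rsq, x$scenario))
  cat(sprintf("  gene CDS = %g bp\n", x$cds_length))
  invisible(x)
}

## Simulate n unascertained subjects for a given gene.
## Returns genotype matrix, retained damage/sign, covariate, latent trait
## and case status. Carriage is generated per variant from its carrier
## probability q_j via sparse carrier lists (most subjects carry nothing).
.simulate_batch <- function(n, gene, config) {
  p <- length(gene$maf)
  geno <- matrix(0L, n, p)
  n_carr <- stats::rbinom(p, n, gene$maf)
  for (j in seq_len(p)) {
    if (n_carr[j] > 0L) geno[sample.int(n, n_carr[j]), j] <- 1L
  }
  carriage <- rowSums(geno) > 0L
  damage <- integer(n)
  vsign <- integer(n)
  idx <- which(carriage)
  if (length(idx)) {
    ## retained variant: maximal damage class, first in gene order on ties
    sub <- geno[idx, , drop = FALSE] *
      matrix(gene$damage_class + 1L, length(idx), p, byrow = TRUE)
    j_star <- max.col(sub, ties.method = "first")
    damage[idx] <- gene$damage_class[j_star]
    vsign[idx] <- gene$sign[j_star]
  }
  d <- switch(config$scenario,
              linear = damage,
              magnitude = as.integer(damage > 0L))
  covariate <- stats::rnorm(n)
  gamma <- sqrt(config$latent_rsq)
  z <- config$delta * vsign * d + gamma * covariate +
    stats::rnorm(n, 0, sqrt(1 - config$latent_rsq))
  list(genotypes = geno, carriage = carriage, damage = damage,
       sign = vsign, covariate = covariate, latent = z,
       y = as.integer(z > stats::qnorm(1 - config$prevalence)))
}

#' Simulate an unascertained population
#'
#' Generates \code{n} subjects from the liability-threshold model without
#' case-control ascertainment: the case fraction is the population
#' prevalence (plus the perturbation induced by the genetic effects).
#'
#' @param n number of subjects.
#' @param config a [sim_config()] object.
#' @param gene an [build_gene()] gene model; by default a fresh gene drawn
#'   from \code{config}.
#' @return a list with elements \code{y}, \code{covariate},
#'   \code{genotypes}, \code{carriage}, \code{damage}, \code{sign},
#'   \code{latent} and \code{gene}.
#' @export
simulate_subjects <- function(n, config = sim_config(), gene = NULL) {
  stopifnot(inherits(config, "rv_sim_config"), n >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(gene))
    gene <- build_gene(config$cds_length, config$class_probs, config$zeta,
                       config$wright)
  out <- .simulate_batch(as.integer(n), gene, config)
  out$gene <- gene
  out
}

#' Simulate an ascertained case-control cohort
#'
#' Subjects are generated from the liability-threshold model
#' (see [sim_config()]) until \code{n_cases} cases and \code{n_controls}
#' controls have been banked (retrospective ascertainment); surplus
#' subjects of either class are discarded in generation order.
#'
#' @param config a [sim_config()] object.
#' @param gene optional [build_gene()] model; a fresh gene is drawn from
#'   \code{config} when omitted (the gene must have been built with the
#'   same \code{zeta} and \code{class_probs} as \code{config}).
#' @return an object of class \code{rv_cohort}: phenotype \code{y} (1 =
#'   case), \code{covariate}, subjects-by-variants carriage matrix
#'   \code{genotypes}, per-subject \code{carriage} indicator, retained
#'   \code{damage} class and \code{sign}, and the \code{gene}.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 50, n_controls = 50, delta = 0.5, zeta = 1,
#'                   seed = 1)
#' coh <- simulate_cohort(cfg)
#' table(coh$y, coh$carriage)
simulate_cohort <- function(config = sim_config(), gene = NULL) {
  stopifnot(inherits(config, "rv_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(gene))
    gene <- build_gene(config$cds_length, config$class_probs, config$zeta,
                       config$wright)
  need_ca <- config$n_cases
  need_co <- config$n_controls
  K <- config$prevalence
  kept <- list()
  generated <- 0L
  while (need_ca > 0L || need_co > 0L) {
    n_batch <- ceiling(1.2 * max(need_ca / K, need_co / (1 - K), 200))
    n_batch <- min(n_batch, config$max_subjects - generated)
    if (n_batch <= 0L)
      stop(sprintf(
        "ascertainment did not complete within the cap of %d generated subjects",
        config$max_subjects))
    b <- .simulate_batch(as.integer(n_batch), gene, config)
    generated <- generated + as.integer(n_batch)
    take_ca <- which(b$y == 1L)[seq_len(min(need_ca, sum(b$y == 1L)))]
    take_co <- which(b$y == 0L)[seq_len(min(need_co, sum(b$y == 0L)))]
    take <- sort(c(take_ca, take_co))
    if (length(take)) {
      kept[[length(kept) + 1L]] <- lapply(
        b[c("y", "covariate", "carriage", "damage", "sign")],
        `[`, take)
      kept[[length(kept)]]$genotypes <- b$genotypes[take, , drop = FALSE]
      need_ca <- need_ca - length(take_ca)
      need_co <- need_co - length(take_co)
    }
  }
  bind <- function(f)
    do.call(if (f == "genotypes") rbind else c, lapply(kept, `[[`, f))
  n <- config$n_cases + config$n_controls
  geno <- bind("genotypes")
  dimnames(geno) <- list(sprintf("S%04d", seq_len(n)),
                         sprintf("var%03d", seq_along(gene$maf)))
  structure(list(y = bind("y"), covariate = bind("covariate"),
                 genotypes = geno, carriage = bind("carriage"),
                 damage = bind("damage"), sign = bind("sign"),
                 gene = gene, config = config),
            class = "rv_cohort")
}

#' @export
print.rv_cohort <- function(x, ...) {
  cat(sprintf("Case-control cohort: %d cases, %d controls, %d variant sites\n",
              sum(x$y == 1), sum(x$y == 0), ncol(x$genotypes)))
  cat(sprintf("  carriers: %d (%.2f%%)\n", sum(x$carriage),
              100 * mean(x$carriage)))
  invisible(x)
}
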