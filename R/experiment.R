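#' Grid specification for size and power experiments
#'
#' Defines the factorial design over effect size \eqn{\delta},
#' heterogeneity \eqn{\zeta}, covariate contribution Rsq and gene CDS
#' length at which empirical size (\eqn{\delta = 0}) or power
#' (\eqn{\delta > 0}) is estimated.
#'
#' @param deltas effect sizes (latent SD units).
#' @param zetas heterogeneity parameter values.
#' @param rsqs covariate variance fractions.
#' @param cds_lengths gene coding lengths in bp (defaults are the 10th,
#'   50th and 90th percentiles of human CDS lengths).
#' @param scenario \code{"linear"} or \code{"magnitude"}.
#' @param n_sims_power simulations per cell for power (\eqn{\delta > 0}).
#' @param n_sims_size simulations per cell for size (\eqn{\delta = 0}).
#' @param alpha nominal type-I-error level at which rejections are
#'   counted.
#' @param methods method tags to run (see [run_rv_tests()]).
#' @param n_resamples Monte-Carlo replicates per test; the default,
#'   \code{10 / alpha}, puts the resampling p-value floor a decade below
#'   \code{alpha}.
#' @return an object of class \code{rv_grid_spec}.
#' @export
grid_spec <- function(deltas = seq(0, 1, by = 0.05),
                      zetas = c(0.5, 0.8, 1),
                      rsqs = c(0, 0.15, 0.30),
                      cds_lengths = c(361, 1209, 4057),
                      scenario = c("linear", "magnitude"),
                      n_sims_power = 250L,
                      n_sims_size = 25000L,
                      alpha = 1e-3,
                      methods = c("TH", "RCS-C", "CA", "CA-P", "SK-R"),
                      n_resamples = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(length(deltas) >= 1, length(zetas) >= 1, length(rsqs) >= 1,
            length(cds_lengths) >= 1, alpha > 0, alpha < 1,
            n_sims_power >= 1, n_sims_size >= 1)
  if (is.null(n_resamples)) n_resamples <- ceiling(10 / alpha)
  structure(list(deltas = deltas, zetas = zetas, rsqs = rsqs,
                 cds_lengths = cds_lengths, scenario = scenario,
                 n_sims_power = as.integer(n_sims_power),
                 n_sims_size = as.integer(n_sims_size), alpha = alpha,
                 methods = methods, n_resamples = as.integer(n_resamples)),
            class = "rv_grid_spec")
}

## run one grid cell: n_sims fresh (gene, cohort) pairs, each analysed by
## every requested method; returns rejection fractions (and p-values).
.run_cell <- function(delta, zeta, rsq, cds, spec, template, seeds) {
  n_sims <- length(seeds)
  pmat <- matrix(NA_real_, n_sims, length(spec$methods),
                 dimnames = list(NULL, spec$methods))
  n_fail <- 0L
  for (s in seq_len(n_sims)) {
    set.seed(seeds[s])
    cfg <- sim_config(n_cases = template$n_cases,
                      n_controls = template$n_controls,
                      prevalence = template$prevalence,
                      rsq = rsq, rsq_scale = template$rsq_scale,
                      delta = delta, zeta = zeta, cds_length = cds,
                      scenario = spec$scenario,
                      class_probs = template$class_probs,
                      wright = template$wright,
                      max_subjects = template$max_subjects)
    coh <- simulate_cohort(cfg)
    covar <- matrix(coh$covariate, ncol = 1)
    res <- try(run_rv_tests(coh$y, coh$genotypes, covar,
                            methods = spec$methods,
                            n_resamples = spec$n_resamples),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      n_fail <- n_fail + 1L
      warning("simulation replicate failed: ", attr(res, "condition")$message)
      next
    }
    pmat[s, res$method] <- res$p_value
  }
  est <- colMeans(pmat <= spec$alpha, na.rm = TRUE)
  out <- data.frame(method = spec$methods, delta = delta, zeta = zeta, rsq = rsq,
             cds_length = cds, scenario = spec$scenario,
             estimate = unname(est),
             mc_se = sqrt(unname(est) * (1 - unname(est)) / n_sims),
             relative_size = unname(est) / spec$alpha,
             n_sims = n_sims, n_failed = n_fail,
             row.names = NULL)
  attr(out, "pvalues") <- pmat
  out
}

.run_grid <- function(spec, template, master_seed, deltas, n_sims,
                      keep_pvalues = FALSE) {
  cells <- expand.grid(delta = deltas, zeta = spec$zetas, rsq = spec$rsqs,
                       cds = spec$cds_lengths, KEEP.OUT.ATTRS = FALSE)
  ## per-replicate seeds derived once from the master seed: reruns with the
  ## same master seed are bit-identical regardless of cell order
  set.seed(master_seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max, nrow(cells) * n_sims),
                     nrow(cells), n_sims)
  out <- vector("list", nrow(cells))
  pvals <- if (keep_pvalues) vector("list", nrow(cells)) else NULL
  for (i in seq_len(nrow(cells))) {
    cell <- .run_cell(cells$delta[i], cells$zeta[i], cells$rsq[i],
                      cells$cds[i], spec, template, seed_mat[i, ])
    out[[i]] <- cell
    if (keep_pvalues) pvals[[i]] <- attr(cell, "pvalues")
  }
  res <- do.call(rbind, out)
  if (keep_pvalues) attr(res, "pvalues") <- pvals
  res
}

#' Empirical size of the tests under the null
#'
#' For every (zeta, Rsq, CDS) cell, simulates \code{n_sims_size}
#' independent gene/cohort pairs with \eqn{\delta = 0} (a fresh gene per
#' replicate), runs each requested method and reports the rejection
#' fraction at \code{alpha} together with its binomial Monte-Carlo
#' standard error and the relative size (estimate / alpha).
#'
#' @param spec a [grid_spec()]; its \code{deltas} are ignored (forced to 0).
#' @param template a [sim_config()] giving sample sizes, prevalence and
#'   Wright hyper-parameters.
#' @param master_seed integer seed from which all per-replicate seeds are
#'   derived.
#' @param keep_pvalues attach the per-replicate p-value matrices as the
#'   \code{"pvalues"} attribute (one matrix per cell).
#' @return data frame of one row per cell x method (class
#'   \code{rv_grid_result}).
#' @export
estimate_size <- function(spec = grid_spec(), template = sim_config(),
                          master_seed = 1L, keep_pvalues = FALSE) {
  res <- .run_grid(spec, template, master_seed, deltas = 0,
                   n_sims = spec$n_sims_size, keep_pvalues = keep_pvalues)
  class(res) <- c("rv_grid_result", class(res))
  res
}

#' Empirical power of the tests
#'
#' Same mechanics as [estimate_size()], over the \eqn{\delta > 0} cells of
#' the grid with \code{n_sims_power} replicates per cell. Rejection is at
#' the same fixed nominal \code{alpha}, so a \eqn{\delta = 0} cell included
#' in \code{deltas} estimates size.
#'
#' @inheritParams estimate_size
#' @export
estimate_power <- function(spec = grid_spec(), template = sim_config(),
                           master_seed = 1L, keep_pvalues = FALSE) {
  res <- .run_grid(spec, template, master_seed, deltas = spec$deltas,
                   n_sims = spec$n_sims_power, keep_pvalues = keep_pvalues)
  class(res) <- c("rv_grid_result", class(res))
  res
}

#' Summarise grid results to CSV (and optionally plot power curves)
#'
#' @param results data frame from [estimate_size()] or [estimate_power()].
#' @param path output CSV path.
#' @param plot_path optional PDF path; one power-curve panel per
#'   (zeta, rsq) combination, power against delta, one line per method and
#'   CDS length.
#' @return invisibly, the results data frame.
#' @export
summarize_grid <- function(results, path, plot_path = NULL) {
  stopifnot(nrow(results) >= 1)
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  if (!is.null(plot_path)) {
    grDevices::pdf(plot_path, width = 9, height = 6)
    on.exit(grDevices::dev.off())
    panels <- unique(results[c("zeta", "rsq")])
    for (k in seq_len(nrow(panels))) {
      sub <- results[results$zeta == panels$zeta[k] &
                       results$rsq == panels$rsq[k], ]
      groups <- unique(sub[c("method", "cds_length")])
      graphics::plot(range(sub$delta), c(0, 1), type = "n", xlab = expression(delta),
           ylab = "empirical power",
           main = sprintf("zeta = %g, Rsq = %g", panels$zeta[k],
                          panels$rsq[k]))
      for (g in seq_len(nrow(groups))) {
        gs <- sub[sub$method == groups$method[g] &
                    sub$cds_length == groups$cds_length[g], ]
        gs <- gs[order(gs$delta), ]
        graphics::lines(gs$delta, gs$estimate, col = g, lty = 1 + (g %% 3))
      }
      graphics::legend("topleft", cex = 0.7,
             legend = sprintf("%s / %d bp", groups$method,
                              groups$cds_length),
             col = seq_len(nrow(groups)),
             lty = 1 + (seq_len(nrow(groups)) %% 3))
    }
  }
  invisible(results)
}
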