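# shared fixtures and oracles built in code

# Wright parameters with beta1 = beta2 = 1 and sigma fixed, so the
# truncated density has the closed form ~ exp(-sigma * p)
flat_wright <- function(sigma = 0) {
  wright_params(beta1_range = c(1, 1), beta2_range = c(1, 1),
                sigma_zero_prob = if (sigma == 0) 1 else 0,
                sigma_range = c(sigma, sigma))
}

# small ascertained cohort for fast method-level tests
quick_cohort <- function(seed, n = 100, delta = 0, zeta = 0.5, rsq = 0.15,
                         cds = 1209) {
  simulate_cohort(sim_config(n_cases = n, n_controls = n, delta = delta,
                             zeta = zeta, rsq = rsq, cds_length = cds,
                             seed = seed))
}

# exact TH resampling p-value by enumerating all carrier-sized subsets
th_enumeration_p <- function(residuals, m, obs) {
  r2 <- (residuals - mean(residuals))^2
  subsets <- utils::combn(length(residuals), m)
  stats <- apply(subsets, 2, function(ix) sum(r2[ix]))
  mean(stats >= obs - 1e-12)
}

# exact C-alpha permutation p-value by enumerating all case-label
# assignments (p0 and c held at their observed values)
calpha_enumeration_p <- function(genotypes, y, obs_T) {
  n <- length(y)
  p0 <- mean(y)
  copy_counts <- colSums(genotypes)
  assignments <- utils::combn(n, sum(y))
  t_star <- apply(assignments, 2, function(ix) {
    yy <- integer(n); yy[ix] <- 1L
    sum((as.vector(crossprod(genotypes, yy)) - copy_counts * p0)^2 -
          copy_counts * p0 * (1 - p0))
  })
  mean(t_star >= obs_T - 1e-12)
}
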