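# shared fixtures: a realistic bolus AIF and small random deconvolution
# problems, all built in code

fixture_grid <- function(dt = 1, n = 40) time_grid(dt, n)

fixture_aif <- function(grid = fixture_grid(), peak = 300, onset = 5,
                        alpha = 3, beta = 1.5) {
  sp <- aif_spec(onset = onset, alpha = alpha, beta = beta)
  sp$amplitude <- aif_amplitude_for_peak(sp, peak)
  make_aif(sp, grid)
}

# bolus-shaped AIF that is nonzero from the first sample, so the Toeplitz
# system is full rank (needed by dense normal-equations oracles)
fullrank_aif <- function(grid, peak = 300, alpha = 3, beta = 1.5) {
  u <- grid_times(grid) + grid$dt
  vals <- u^alpha * exp(-u / beta)
  concentration_curve(grid, vals / max(vals) * peak, "arterial")
}

# smooth exponential flow-scaled residue with random physiologic parameters
random_k <- function(grid, cbf = stats::runif(1, 20, 80),
                     mtt = stats::runif(1, 2, 8)) {
  flow_scaled_residue(tissue_kinetics(cbf = cbf, mtt = mtt), grid)
}

# realistic bolus problem: gamma-variate AIF with onset delay, so the
# Toeplitz system is severely ill conditioned (the clinically relevant
# regime that motivates regularization)
bolus_problem <- function(n = 40, dt = 1, noise_frac = 0) {
  grid <- time_grid(dt, n)
  aif <- fixture_aif(grid, onset = stats::runif(1, 2, 5))
  k <- random_k(grid)
  cv <- forward_convolve(aif, k)
  if (noise_frac > 0)
    cv <- concentration_curve(
      grid, cv$values + stats::rnorm(n, 0, noise_frac * max(cv$values)),
      "tissue")
  list(grid = grid, aif = aif, k_true = k, c_voi = cv)
}

# aif + tissue curve + truth for a random deconvolution problem; the
# full-rank AIF keeps dense oracles (normal equations) well defined
random_problem <- function(n = 32, dt = 1, noise_frac = 0,
                           alpha = stats::runif(1, 2, 4),
                           beta = stats::runif(1, 1, 2)) {
  grid <- time_grid(dt, n)
  aif <- fullrank_aif(grid, peak = stats::runif(1, 100, 400),
                      alpha = alpha, beta = beta)
  k <- random_k(grid)
  cv <- forward_convolve(aif, k)
  if (noise_frac > 0)
    cv <- concentration_curve(
      grid, cv$values + stats::rnorm(n, 0, noise_frac * max(cv$values)),
      "tissue")
  list(grid = grid, aif = aif, k_true = k, c_voi = cv)
}
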