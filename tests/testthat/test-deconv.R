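test_that("Toeplitz matrix follows the printed construction", {
  grid <- time_grid(1, 3)
  aif <- concentration_curve(grid, c(1, 2, 3), "arterial")
  A <- build_system_matrix(aif, "toeplitz")
  expect_equal(A$A[, 1], c(1, 2, 3))
  expect_equal(A$A[1, ], c(1, 0, 0))
  expect_equal(A$A[3, ], c(3, 2, 1))
  zero <- concentration_curve(grid, rep(0, 3), "arterial")
  expect_error(build_system_matrix(zero), "identically zero")
})

test_that("leading AIF zeros bound the matrix rank", {
  grid <- time_grid(1, 20)
  vals <- c(0, 0, fullrank_aif(time_grid(1, 18))$values)
  A <- build_system_matrix(concentration_curve(grid, vals, "arterial"),
                           "toeplitz")
  expect_equal(A$n_lz, 2L)
  expect_lte(A$svd$rank, A$N - 2L)
})

test_that("circulant product equals brute-force circular convolution", {
  grid <- time_grid(1, 3)
  A <- build_system_matrix(concentration_curve(grid, c(1, 0, 0),
                                               "arterial"), "circulant")
  expect_equal(A$L, 6L)
  set.seed(3)
  x <- rnorm(6)
  col1 <- A$A[, 1]
  brute <- vapply(1:6, function(i)
    sum(vapply(1:6, function(j) col1[((i - j) %% 6) + 1] * x[j],
               numeric(1))), numeric(1))
  expect_equal(as.vector(A$A %*% x), brute, tolerance = 1e-12)
  # first-column circulant of an impulse is the scaled identity
  expect_equal(A$A, diag(6))
})

test_that("least squares inverts exact data and blows up on noise", {
  set.seed(21)
  # well-conditioned full-rank system: exact inversion, QR oracle
  grid <- time_grid(1, 32)
  aif <- concentration_curve(grid, 300 * exp(-grid_times(grid) / 8),
                             "arterial")
  A <- build_system_matrix(aif, "toeplitz")
  k <- random_k(grid, 60, 4)
  cv <- forward_convolve(aif, k)
  sol <- least_squares_solution(A, cv)
  expect_equal(sol$values, k$values, tolerance = 1e-8)
  expect_equal(sol$values, qr.solve(A$A, cv$values), tolerance = 1e-10)
  zero <- concentration_curve(grid, rep(0, 32), "tissue")
  expect_equal(least_squares_solution(A, zero)$values, rep(0, 32))
  # phantom AIF + 1% noise: amplitudes explode far beyond physiology and
  # the solution oscillates much more than a regularized one
  ph <- render_acquisition(reference_phantom())
  conv <- ct_to_concentration(ph$series)
  An <- build_system_matrix(ph$truth$aif, "toeplitz")
  ktrue <- flow_scaled_residue(tissue_kinetics(cbf = 60, cbv = 4),
                               conv$grid)
  cl <- concentration_curve(conv$grid, conv$conc[6, 2, 1, ], "tissue")
  noisy_c <- concentration_curve(
    conv$grid, cl$values + rnorm(conv$grid$n, 0, 0.01 * max(cl$values)),
    "tissue")
  noisy <- least_squares_solution(An, noisy_c)
  expect_gt(max(abs(noisy$values)), 100 * max(ktrue$values))
  reg <- regularized_solution(An, noisy_c,
                              regularization_spec("tikhonov", 0.3))
  expect_gt(noisy$diagnostics$oscillation_index,
            5 * reg$diagnostics$oscillation_index)
})

test_that("Tikhonov SVD solution equals the normal-equations minimizer", {
  set.seed(33)
  for (trial in 1:25) {
    n <- sample(8:64, 1)
    p <- random_problem(n = n, noise_frac = 0.02)
    A <- build_system_matrix(p$aif, "toeplitz")
    lam_rel <- 10^runif(1, -3, -0.3)
    sol <- regularized_solution(
      A, p$c_voi, regularization_spec("tikhonov", lam_rel))
    lam <- lam_rel * A$svd$d[1]
    oracle <- solve(crossprod(A$A) + lam^2 * diag(n),
                    crossprod(A$A, p$c_voi$values))[, 1]
    expect_equal(sol$values, oracle, tolerance = 1e-8)
  }
})

test_that("regularization limits: lambda -> 0 and TSVD truncation edges", {
  set.seed(7)
  p <- random_problem(n = 24)
  A <- build_system_matrix(p$aif, "toeplitz")
  ls <- least_squares_solution(A, p$c_voi)
  tik <- regularized_solution(A, p$c_voi,
                              regularization_spec("tikhonov", 1e-9))
  expect_equal(tik$values, ls$values, tolerance = 1e-6)
  # TSVD with lambda just below sigma_r keeps every component
  lam_edge <- 0.999 * A$svd$d[A$svd$rank] / A$svd$d[1]
  tsvd <- regularized_solution(A, p$c_voi,
                               regularization_spec("tsvd", lam_edge))
  expect_equal(tsvd$values, ls$values, tolerance = 1e-10)
  expect_error(regularized_solution(
    A, p$c_voi, regularization_spec("tikhonov", 1.5)), "lambda_rel")
})

test_that("solution and residual norms are monotone in lambda", {
  set.seed(55)
  lams <- 10^seq(-4, 0, length.out = 50)
  for (trial in 1:20) {
    p <- random_problem(n = 24, noise_frac = 0.02)
    A <- build_system_matrix(p$aif, "toeplitz")
    norms <- t(vapply(lams, function(l) {
      s <- regularized_solution(A, p$c_voi,
                                regularization_spec("tikhonov", l))
      c(s$diagnostics$solution_norm, s$diagnostics$residual_norm)
    }, numeric(2)))
    expect_true(all(diff(norms[, 1]) <= 1e-10 * norms[1, 1]))
    expect_true(all(diff(norms[, 2]) >= -1e-10 * max(norms[, 2])))
  }
})

test_that("FFT path reproduces circulant Tikhonov and exact inversion", {
  set.seed(9)
  p <- random_problem(n = 32)
  Ac <- build_system_matrix(p$aif, "circulant")
  for (lam in c(0.01, 0.1, 0.3)) {
    sc <- regularized_solution(Ac, p$c_voi,
                               regularization_spec("tikhonov", lam))
    sf <- fft_deconvolve(p$aif, p$c_voi, lam)
    expect_equal(sf$values, sc$values,
                 tolerance = 1e-6 * max(abs(sc$values)))
  }
  # noiseless consistent data, tiny lambda: recovers k
  sf0 <- fft_deconvolve(p$aif, p$c_voi, 1e-8)
  expect_equal(sf0$values, p$k_true$values, tolerance = 1e-5)
  # impulse AIF: k = c / (dt * peak) up to the filter
  grid <- p$grid
  imp <- concentration_curve(grid, c(2, rep(0, 31)), "arterial")
  cv <- forward_convolve(imp, p$k_true)
  ki <- fft_deconvolve(imp, cv, 1e-10)
  expect_equal(ki$values, cv$values / (grid$dt * 2), tolerance = 1e-6)
})

test_that("circulant deconvolution is insensitive to bolus delay", {
  set.seed(13)
  p <- random_problem(n = 40)
  Ac <- build_system_matrix(p$aif, "circulant")
  At <- build_system_matrix(p$aif, "toeplitz")
  d <- 3L
  shifted <- concentration_curve(
    p$grid, c(rep(0, d), p$c_voi$values[seq_len(40 - d)]), "tissue")
  spec <- regularization_spec("tikhonov", 0.1)
  mc0 <- max(regularized_solution(Ac, p$c_voi, spec)$values)
  mc3 <- max(regularized_solution(Ac, shifted, spec)$values)
  expect_lt(abs(mc3 - mc0) / mc0, 0.02)
  mt0 <- max(regularized_solution(At, p$c_voi, spec)$values)
  mt3 <- max(regularized_solution(At, shifted, spec)$values)
  expect_lt(mt3, mt0)
  # TMAX shifts by exactly d samples on the circulant path
  t0 <- tmax_of_k(regularized_solution(Ac, p$c_voi, spec))
  t3 <- tmax_of_k(regularized_solution(Ac, shifted, spec))
  expect_equal(t3 - t0, d * p$grid$dt)
})

test_that("model-based exponential fit recovers matching truth", {
  set.seed(17)
  grid <- time_grid(1, 40)
  aif <- fixture_aif(grid)
  tk <- tissue_kinetics(cbf = 60, mtt = 4)
  k <- flow_scaled_residue(tk, grid)
  cv <- forward_convolve(aif, k)
  fit <- model_fit_deconvolve(aif, cv)
  expect_equal(fit$cbf_scaled, max(k$values), tolerance = 0.01)
  expect_equal(fit$mtt_model, 4, tolerance = 0.01)
  expect_false(fit$degenerate)
  # gamma-shaped residue: b biased but the product a*b (CBV) is preserved
  kg <- flow_scaled_residue(
    tissue_kinetics(cbf = 60, mtt = 4, residue_family = "gamma"), grid)
  cg <- forward_convolve(aif, kg)
  fg <- model_fit_deconvolve(aif, cg)
  truth_area <- grid$dt * sum(kg$values)
  expect_equal(fg$cbf_scaled * fg$mtt_model, truth_area, tolerance = 0.05)
  # zero curve
  z <- concentration_curve(grid, rep(0, 40), "tissue")
  expect_equal(model_fit_deconvolve(aif, z)$cbf_scaled, 0)
})

test_that("Picard diagnostic flags noise-dominated coefficients", {
  set.seed(29)
  ph <- render_acquisition(reference_phantom())
  conv <- ct_to_concentration(ph$series)
  A <- build_system_matrix(ph$truth$aif, "toeplitz")
  # consistent data in the span of the first singular vector
  c1 <- A$svd$d[1] * A$svd$u[, 1]
  d1 <- picard_diagnostic(A, c1)
  expect_false(d1$violated)
  expect_lt(d1$table$utc[5] / d1$table$utc[1], 1e-8)
  # white noise violates the decay condition
  dn <- picard_diagnostic(A, rnorm(conv$grid$n))
  expect_true(dn$violated)
  # noiseless consistent tissue curve: not violated; noisy: violated
  cl <- conv$conc[6, 2, 1, ]
  expect_false(picard_diagnostic(A, cl)$violated)
  noisy <- cl + rnorm(conv$grid$n, 0, 0.01 * max(cl))
  expect_true(picard_diagnostic(A, noisy)$violated)
})

test_that("oscillation index is zero for affine k and exact for alternating", {
  expect_equal(oscillation_index(rep(2, 10)), 0)
  expect_equal(oscillation_index(seq(0, 9)), 0)
  L <- 12
  alt <- rep(c(1, -1), L / 2)
  expect_equal(oscillation_index(alt), (L - 2) * 2 / L)
  expect_true(is.na(oscillation_index(c(-1, -2, -1))))
})

test_that("OI-threshold selection regularizes more under noise", {
  set.seed(41)
  p <- random_problem(n = 32)
  A <- build_system_matrix(p$aif, "toeplitz")
  spec <- regularization_spec("tikhonov", selection = "oi",
                              oi_threshold = 0.1)
  lam_clean <- select_lambda_oi(A, p$c_voi, spec)
  noisy <- concentration_curve(
    p$grid, p$c_voi$values + rnorm(32, 0, 0.05 * max(p$c_voi$values)),
    "tissue")
  lam_noisy <- select_lambda_oi(A, noisy, spec)
  expect_gt(lam_noisy, lam_clean)
  expect_equal(lam_clean, 1e-4) # smooth noiseless data: grid minimum
  spec_inf <- regularization_spec("tikhonov", selection = "oi",
                                  oi_threshold = Inf)
  expect_equal(select_lambda_oi(A, noisy, spec_inf), 1e-4)
})

test_that("L-curve corner matches a brute-force curvature oracle", {
  set.seed(47)
  p <- random_problem(n = 32, noise_frac = 0.02)
  A <- build_system_matrix(p$aif, "toeplitz")
  spec <- regularization_spec("tikhonov", selection = "lcurve")
  lam <- select_lambda_lcurve(A, p$c_voi, spec)
  # oracle: dense normal-equations solves + direct curvature formula
  grid_l <- 10^seq(-4, 0, length.out = 50)
  pts <- t(vapply(grid_l, function(l) {
    lam_abs <- l * A$svd$d[1]
    kk <- solve(crossprod(A$A) + lam_abs^2 * diag(32),
                crossprod(A$A, p$c_voi$values))[, 1]
    c(log(sum((A$A %*% kk - p$c_voi$values)^2)), log(sum(kk^2)))
  }, numeric(2)))
  curv <- vapply(2:49, function(i) {
    a <- pts[i - 1, ]; b <- pts[i, ]; cc <- pts[i + 1, ]
    cross <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    2 * abs(cross) / (sqrt(sum((b - a)^2)) * sqrt(sum((cc - b)^2)) *
                        sqrt(sum((cc - a)^2)))
  }, numeric(1))
  best <- grid_l[1 + which.max(curv)]
  idx_sel <- which.min(abs(grid_l - lam))
  idx_best <- which.min(abs(grid_l - best))
  expect_lte(abs(idx_sel - idx_best), 1)
  # too-short grid errors
  expect_error(select_lambda_lcurve(
    A, p$c_voi, regularization_spec("tikhonov", selection = "lcurve",
                                    lcurve_grid = 2)), ">= 10")
})
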