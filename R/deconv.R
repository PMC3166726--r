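#' System matrix of the discrete convolution
#'
#' Builds the matrix form `A k = c` of the discrete indicator-dilution
#' equation. The Toeplitz form is the N x N lower-triangular matrix with
#' constant diagonals and first column `dt * c_art(t_1..t_N)`. The
#' block-circulant form zero-pads the AIF to `L = 2N` and builds the L x L
#' circulant whose columns are circular downshifts of the padded first
#' column; it makes the deconvolution insensitive to bolus delay (a pure
#' integer delay of the tissue curve circularly shifts k without attenuating
#' its maximum). The SVD is computed on construction and cached.
#'
#' @param aif Arterial [concentration_curve()] on a uniform grid.
#' @param kind `"toeplitz"` or `"circulant"`.
#' @param svd_tol Relative singular-value cutoff defining the numerical
#'   rank (default 1e-12).
#' @return An object of class `system_matrix` with fields `A`, `kind`,
#'   `grid`, `N`, `L`, `n_lz` (leading zeros of the AIF), and cached `svd`
#'   (`u`, `d`, `v`, `rank`).
#' @export
build_system_matrix <- function(aif, kind = c("toeplitz", "circulant"),
                                svd_tol = 1e-12) {
  stopifnot(inherits(aif, "concentration_curve"))
  kind <- match.arg(kind)
  a <- aif$values
  if (all(a == 0)) stop("AIF is identically zero")
  N <- aif$grid$n
  dt <- aif$grid$dt
  n_lz <- if (a[1] != 0) 0L else which(a != 0)[1] - 1L
  if (kind == "toeplitz") {
    col1 <- dt * a
    A <- matrix(0, N, N)
    for (j in seq_len(N)) A[j:N, j] <- col1[seq_len(N - j + 1)]
    L <- N
  } else {
    L <- 2L * N
    col1 <- dt * c(a, rep(0, N))
    idx <- outer(seq_len(L), seq_len(L), function(i, j) ((i - j) %% L) + 1L)
    A <- matrix(col1[idx], L, L)
  }
  sv <- svd(A)
  rank <- sum(sv$d > svd_tol * sv$d[1])
  structure(list(A = A, kind = kind, grid = aif$grid, N = N, L = L,
                 dt = dt, n_lz = n_lz,
                 svd = list(u = sv$u, d = sv$d, v = sv$v, rank = rank)),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf(
    "system_matrix [%s]: %d x %d, rank %d, cond sigma1/sigmar = %.3g\n",
    x$kind, x$L, x$L, x$svd$rank, x$svd$d[1] / x$svd$d[x$svd$rank]))
  invisible(x)
}

# pad/truncate the tissue vector for the chosen matrix kind
rhs_vector <- function(A, c_voi) {
  v <- if (inherits(c_voi, "concentration_curve")) c_voi$values else c_voi
  stopifnot(length(v) == A$N)
  if (A$kind == "circulant") c(v, rep(0, A$N)) else v
}

# filtered SVD solve; f = filter factors over retained components
svd_solve <- function(A, cvec, filter_factors) {
  sv <- A$svd
  r <- sv$rank
  coef <- crossprod(sv$u[, seq_len(r), drop = FALSE], cvec)[, 1] /
    sv$d[seq_len(r)]
  k <- sv$v[, seq_len(r), drop = FALSE] %*% (filter_factors * coef)
  k[, 1]
}

solution_diagnostics <- function(A, cvec, kfull, lambda_rel) {
  res <- sqrt(sum((A$A %*% kfull - cvec)^2))
  list(residual_norm = res,
       solution_norm = sqrt(sum(kfull^2)),
       lambda_rel_used = lambda_rel)
}

finish_solution <- function(A, cvec, kfull, lambda_rel) {
  diag <- solution_diagnostics(A, cvec, kfull, lambda_rel)
  k <- kfull[seq_len(A$N)] # drop circulant padding
  out <- new_flow_scaled_residue(A$grid, k, diag)
  out$diagnostics$oscillation_index <- oscillation_index(out)
  out
}

#' Unregularized least-squares deconvolution
#'
#' The minimizer of the squared residual norm, computed from the SVD as the
#' sum over retained singular triplets of `(u_i' c / sigma_i) v_i`. For the
#' ill-conditioned Toeplitz system this solution oscillates strongly under
#' even mild noise (the discrete Picard condition is violated); it exists
#' for diagnostic purposes and as the regularized solutions' limit.
#'
#' @param A A [build_system_matrix()] result.
#' @param c_voi Tissue [concentration_curve()] (or numeric vector, length N).
#' @return A `flow_scaled_residue` with diagnostics (`residual_norm`,
#'   `solution_norm`, `oscillation_index`, `lambda_rel_used = 0`,
#'   `picard_flag`).
#' @export
least_squares_solution <- function(A, c_voi) {
  stopifnot(inherits(A, "system_matrix"))
  cvec <- rhs_vector(A, c_voi)
  kfull <- svd_solve(A, cvec, rep(1, A$svd$rank))
  out <- finish_solution(A, cvec, kfull, lambda_rel = 0)
  out$diagnostics$picard_flag <- picard_diagnostic(A, c_voi)$violated
  out
}

#' Regularization specification
#'
#' @param method `"tikhonov"` (smooth filter factors
#'   `sigma^2/(sigma^2+lambda^2)`) or `"tsvd"` (hard truncation at
#'   `sigma < lambda`).
#' @param lambda_rel Relative regularization parameter in (0, 1]; the
#'   absolute parameter is `lambda = lambda_rel * sigma_1`. Default 0.2, a
#'   typical fixed value in brain perfusion CT.
#' @param selection `"fixed"`, `"oi"` (oscillation-index threshold), or
#'   `"lcurve"` (L-curve corner).
#' @param oi_threshold Oscillation-index threshold for `selection = "oi"`
#'   (default 0.1).
#' @param lcurve_grid Number of log-spaced candidate `lambda_rel` values in
#'   `[1e-4, 1]` used by the `"oi"` and `"lcurve"` selectors (default 50).
#' @return An object of class `regularization_spec`.
#' @export
regularization_spec <- function(method = c("tikhonov", "tsvd"),
                                lambda_rel = 0.2,
                                selection = c("fixed", "oi", "lcurve"),
                                oi_threshold = 0.1,
                                lcurve_grid = 50L) {
  method <- match.arg(method)
  selection <- match.arg(selection)
  if (selection == "fixed") {
    if (!is.numeric(lambda_rel) || lambda_rel <= 0 || lambda_rel > 1)
      stop("lambda_rel must lie in (0, 1]")
  }
  structure(list(method = method, lambda_rel = lambda_rel,
                 selection = selection, oi_threshold = oi_threshold,
                 lcurve_grid = as.integer(lcurve_grid)),
            class = "regularization_spec")
}

lambda_grid <- function(spec) {
  10^seq(log10(1e-4), 0, length.out = spec$lcurve_grid)
}

filter_factors <- function(A, method, lambda_rel) {
  sv <- A$svd
  sig <- sv$d[seq_len(sv$rank)]
  lam <- lambda_rel * sig[1]
  if (method == "tsvd") as.numeric(sig >= lam) else sig^2 / (sig^2 + lam^2)
}

#' Regularized SVD deconvolution
#'
#' Filtered SVD solution `k_lambda = sum f_i (u_i' c / sigma_i) v_i` with
#' TSVD or Tikhonov filter factors and `lambda = lambda_rel * sigma_1`. The
#' Tikhonov solution equals the minimizer of
#' `|A k - c|^2 + lambda^2 |k|^2`. If the spec requests `"oi"` or
#' `"lcurve"` selection, the parameter is chosen first via
#' [select_lambda_oi()] or [select_lambda_lcurve()].
#'
#' @inheritParams least_squares_solution
#' @param spec A [regularization_spec()].
#' @return A `flow_scaled_residue` with diagnostics.
#' @export
regularized_solution <- function(A, c_voi, spec = regularization_spec()) {
  stopifnot(inherits(A, "system_matrix"),
            inherits(spec, "regularization_spec"))
  lam_rel <- switch(spec$selection,
                    fixed = spec$lambda_rel,
                    oi = select_lambda_oi(A, c_voi, spec),
                    lcurve = select_lambda_lcurve(A, c_voi, spec))
  if (lam_rel <= 0 || lam_rel > 1) stop("lambda_rel must lie in (0, 1]")
  cvec <- rhs_vector(A, c_voi)
  f <- filter_factors(A, spec$method, lam_rel)
  kfull <- svd_solve(A, cvec, f)
  out <- finish_solution(A, cvec, kfull, lambda_rel = lam_rel)
  out$diagnostics$method <- spec$method
  out$diagnostics$matrix_kind <- A$kind
  out
}

#' Fourier-domain deconvolution
#'
#' Deconvolution via the discrete Fourier transform with a Tikhonov-matched
#' Wiener filter: with `Ahat = fft(dt * zero-padded AIF)` (the circulant
#' eigenvalues, whose moduli are the circulant singular values),
#' `khat = conj(Ahat) * chat / (|Ahat|^2 + lambda^2)` and
#' `lambda = lambda_rel * max |Ahat|`. This is algebraically identical to
#' Tikhonov filtering of the block-circulant SVD, and is O(N log N) instead
#' of O(N^3).
#'
#' @param aif Arterial [concentration_curve()].
#' @param c_voi Tissue [concentration_curve()] on the same grid.
#' @param lambda_rel Relative regularization parameter (0 allowed only when
#'   no Fourier coefficient of the padded AIF vanishes).
#' @return A `flow_scaled_residue` (first N samples of the padded solution).
#' @export
fft_deconvolve <- function(aif, c_voi, lambda_rel = 0.2) {
  stopifnot(inherits(aif, "concentration_curve"),
            inherits(c_voi, "concentration_curve"))
  if (!same_grid(aif$grid, c_voi$grid))
    stop("aif and c_voi are on different time grids")
  N <- aif$grid$n
  L <- 2L * N
  Ahat <- stats::fft(c(aif$grid$dt * aif$values, rep(0, N)))
  Chat <- stats::fft(c(c_voi$values, rep(0, N)))
  mods <- Mod(Ahat)
  if (lambda_rel == 0 && any(mods == 0))
    stop("unregularized division by zero: AIF has vanishing Fourier coefficients")
  lam <- lambda_rel * max(mods)
  Khat <- Conj(Ahat) * Chat / (mods^2 + lam^2)
  kfull <- Re(stats::fft(Khat, inverse = TRUE)) / L
  res <- sqrt(sum(Mod(Ahat * Khat / L - Chat / L)^2) * L) # Parseval
  out <- new_flow_scaled_residue(
    aif$grid, kfull[seq_len(N)],
    list(residual_norm = res, solution_norm = sqrt(sum(kfull^2)),
         lambda_rel_used = lambda_rel, method = "tikhonov",
         matrix_kind = "fft"))
  out$diagnostics$oscillation_index <- oscillation_index(out)
  out
}

#' Model-based deconvolution with an exponential residue
#'
#' Fits `k_model(t) = a * exp(-t/b)` (a = CBF * rho_voi, b = MTT) by
#' minimizing the squared misfit between `forward_convolve(aif, k_model)`
#' and the measured tissue curve. Restricting k to a decaying exponential
#' makes the deconvolution stable at the cost of bias when the true residue
#' has a different shape (CBV = a*b is largely preserved). The amplitude is
#' solved in closed form for each candidate b on a coarse log grid, followed
#' by local refinement; the procedure is deterministic.
#'
#' @param aif Arterial [concentration_curve()].
#' @param c_voi Tissue [concentration_curve()] on the same grid.
#' @param b_range Search range for the time constant b in seconds.
#' @return List with `cbf_scaled` (a, 1/s), `mtt_model` (b, s), `k` (the
#'   fitted `flow_scaled_residue`) and `degenerate` flag (b at a search
#'   bound).
#' @export
model_fit_deconvolve <- function(aif, c_voi, b_range = c(0.2, 40)) {
  stopifnot(inherits(aif, "concentration_curve"),
            inherits(c_voi, "concentration_curve"))
  if (!same_grid(aif$grid, c_voi$grid))
    stop("aif and c_voi are on different time grids")
  tt <- grid_times(aif$grid)
  dt <- aif$grid$dt
  cv <- c_voi$values
  sse_of <- function(b) {
    basis <- dt * causal_convolve(aif$values, exp(-tt / b))
    denom <- sum(basis^2)
    a <- if (denom > 0) max(0, sum(basis * cv) / denom) else 0
    c(sse = sum((a * basis - cv)^2), a = a)
  }
  if (all(cv == 0)) {
    k <- new_flow_scaled_residue(aif$grid, rep(0, aif$grid$n),
                                 list(method = "model_fit"))
    return(list(cbf_scaled = 0, mtt_model = NA_real_, k = k,
                degenerate = TRUE))
  }
  bs <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = 60))
  coarse <- vapply(bs, function(b) sse_of(b)["sse"], numeric(1))
  i <- which.min(coarse)
  lo <- bs[max(1L, i - 1L)]; hi <- bs[min(length(bs), i + 1L)]
  opt <- stats::optimize(function(b) sse_of(b)["sse"], c(lo, hi),
                         tol = 1e-6)
  b <- opt$minimum
  a <- sse_of(b)["a"]
  degenerate <- (b / b_range[1] < 1.05) || (b_range[2] / b < 1.05)
  k <- new_flow_scaled_residue(aif$grid, a * exp(-tt / b),
                               list(method = "model_fit",
                                    lambda_rel_used = NA_real_))
  list(cbf_scaled = unname(a), mtt_model = b, k = k, degenerate = degenerate)
}

#' Discrete Picard diagnostic
#'
#' Tabulates, per singular index, the singular value `sigma_i`, the Fourier
#' coefficient magnitude `|u_i' c|` and their ratio (the weight of the i-th
#' right singular vector in the least-squares solution). The discrete
#' Picard condition is violated when the coefficients fail to decay faster
#' than the singular values — the usual signature of noise-dominated
#' components. The flag compares the geometric mean of the ratios over a
#' trailing window against a leading window (violated when > 10x).
#'
#' @param A A [build_system_matrix()] result.
#' @param c_voi Tissue curve (vector or `concentration_curve`).
#' @param window Window length for the leading/trailing comparison.
#' @return List with `table` (data.frame: index, sigma, utc, ratio) and
#'   `violated` flag.
#' @export
picard_diagnostic <- function(A, c_voi, window = 5L) {
  stopifnot(inherits(A, "system_matrix"))
  cvec <- rhs_vector(A, c_voi)
  sv <- A$svd
  r <- sv$rank
  utc <- abs(crossprod(sv$u[, seq_len(r), drop = FALSE], cvec)[, 1])
  sig <- sv$d[seq_len(r)]
  ratio <- utc / sig
  w <- min(as.integer(window), r %/% 2L)
  violated <- FALSE
  if (w >= 1L) {
    gm <- function(x) exp(mean(log(pmax(x, .Machine$double.xmin))))
    lead <- ratio[seq_len(w)]
    trail <- ratio[seq.int(r - w + 1L, r)]
    violated <- all(trail > 0) && gm(trail) > 10 * gm(lead)
  }
  list(table = data.frame(index = seq_len(r), sigma = sig, utc = utc,
                          ratio = ratio),
       violated = violated)
}

#' Oscillation index of a flow-scaled residue
#'
#' `OI = (1/L) * (1/max k) * sum_{j=3}^{L} |k_j - 2 k_{j-1} + k_{j-2}| / 2`,
#' a normalized mean absolute second difference. OI is zero for affine k
#' and grows with nonphysiological oscillation; it drives the
#' oscillation-index regularization selector.
#'
#' @param k A `flow_scaled_residue` (or numeric vector of length >= 3).
#' @return Non-negative scalar; `NA` when `max(k) <= 0`.
#' @export
oscillation_index <- function(k) {
  v <- if (inherits(k, "flow_scaled_residue")) k$values else as.numeric(k)
  L <- length(v)
  stopifnot(L >= 3L)
  m <- max(v)
  if (m <= 0) return(NA_real_)
  sum(abs(diff(v, differences = 2L))) / (2 * L * m)
}

#' Select lambda by oscillation-index threshold
#'
#' Scans the log-spaced candidate grid from weak to strong regularization
#' and returns the smallest `lambda_rel` whose solution has an oscillation
#' index below the threshold. If no candidate passes, the grid maximum is
#' returned with a warning.
#'
#' @inheritParams regularized_solution
#' @return Selected `lambda_rel`.
#' @export
select_lambda_oi <- function(A, c_voi, spec = regularization_spec(selection = "oi")) {
  stopifnot(spec$oi_threshold > 0)
  grid <- lambda_grid(spec)
  for (lam in grid) {
    sol <- regularized_solution(
      A, c_voi, regularization_spec(spec$method, lambda_rel = lam))
    oi <- sol$diagnostics$oscillation_index
    if (!is.na(oi) && oi < spec$oi_threshold) return(lam)
  }
  warning("no lambda_rel on the grid meets the OI threshold; using grid max")
  grid[length(grid)]
}

#' Select lambda by L-curve corner
#'
#' Evaluates the L-curve — log squared residual norm versus log squared
#' solution norm over the candidate grid — and returns the `lambda_rel` at
#' the point of maximum Menger curvature over consecutive triples (the
#' characteristic corner). Ties break toward smaller lambda. A degenerate
#' (collinear) curve falls back to the fixed default 0.2 with a warning.
#'
#' @inheritParams regularized_solution
#' @return Selected `lambda_rel`.
#' @export
select_lambda_lcurve <- function(A, c_voi,
                                 spec = regularization_spec(selection = "lcurve")) {
  grid <- lambda_grid(spec)
  if (length(grid) < 10L) stop("L-curve selection needs >= 10 grid points")
  pts <- t(vapply(grid, function(lam) {
    sol <- regularized_solution(
      A, c_voi, regularization_spec(spec$method, lambda_rel = lam))
    c(log(sol$diagnostics$residual_norm^2 + .Machine$double.xmin),
      log(sol$diagnostics$solution_norm^2 + .Machine$double.xmin))
  }, numeric(2)))
  curv <- menger_curvature(pts)
  if (all(!is.finite(curv)) || max(curv, na.rm = TRUE) <= 1e-12) {
    warning("degenerate L-curve; falling back to lambda_rel = 0.2")
    return(0.2)
  }
  grid[which.max(curv)] # which.max: first (= smallest lambda) on ties
}

# Menger curvature at each interior point of a polyline; end points get 0
menger_curvature <- function(pts) {
  n <- nrow(pts)
  curv <- numeric(n)
  for (i in seq.int(2L, n - 1L)) {
    p <- pts[i - 1L, ]; q <- pts[i, ]; s <- pts[i + 1L, ]
    cross <- (q[1] - p[1]) * (s[2] - p[2]) - (q[2] - p[2]) * (s[1] - p[1])
    d1 <- sqrt(sum((q - p)^2)); d2 <- sqrt(sum((s - q)^2))
    d3 <- sqrt(sum((s - p)^2))
    denom <- d1 * d2 * d3
    curv[i] <- if (denom > 0) 2 * abs(cross) / denom else 0
  }
  curv
}
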