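#' Dynamic acquisition series
#'
#' A raw 4D dynamic series: CT attenuation in HU or MR signal in arbitrary
#' (positive) units, sampled on a uniform frame grid. The first
#' `baseline_frames` frames are acquired before the contrast bolus arrives
#' and define the per-voxel baseline for the concentration conversion.
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param modality `"CT"` or `"MR"`.
#' @param dt Frame interval in seconds.
#' @param baseline_frames Number of baseline frames B (>= 1, < n frames).
#' @param te MR echo time in seconds (required for MR).
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(data, modality = c("CT", "MR"), dt,
                               baseline_frames, te = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.array(data), length(dim(data)) == 4L)
  B <- as.integer(baseline_frames)
  n_frames <- dim(data)[4]
  if (B < 1L || B >= n_frames)
    stop("baseline_frames must satisfy 1 <= B < number of frames")
  if (modality == "MR" && (is.null(te) || te <= 0))
    stop("MR series requires a positive echo time te")
  structure(list(data = data, modality = modality,
                 grid = time_grid(dt, n_frames),
                 baseline_frames = B, te = te),
            class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("acquisition_series [%s]: %d x %d x %d voxels, %d frames, dt = %g s, B = %d\n",
              x$modality, d[1], d[2], d[3], d[4], x$grid$dt,
              x$baseline_frames))
  invisible(x)
}

#' Conversion configuration
#'
#' Constants of the signal-to-concentration conversion and related
#' corrections. `k_ct` defaults to 1 g/mL/HU — the proportionality constant
#' drops out of the deconvolution, so unity is the standard choice. `kappa`
#' is the hematocrit correction (contrast agent distributes in plasma only,
#' and the plasma fraction differs between arteries and capillaries);
#' 0.73 is the commonly used value. MR proportionality can differ between
#' blood and tissue; both knobs default to 1.
#'
#' @param k_ct CT proportionality, g/mL/HU (> 0).
#' @param k_mr MR proportionality (> 0); sets both blood and tissue values
#'   unless overridden.
#' @param k_mr_blood,k_mr_tissue Separate MR proportionalities.
#' @param kappa Hematocrit correction factor in (0, 1].
#' @param apply_hct Apply kappa to tissue curves (default TRUE; arterial
#'   and venous curves are never scaled).
#' @param smoothing_sigma_vox Isotropic Gaussian smoothing sigma in voxels
#'   (0 = off).
#' @return An object of class `conversion_config`.
#' @export
conversion_config <- function(k_ct = 1, k_mr = 1, k_mr_blood = k_mr,
                              k_mr_tissue = k_mr, kappa = 0.73,
                              apply_hct = TRUE, smoothing_sigma_vox = 0) {
  stopifnot(k_ct > 0, k_mr > 0, k_mr_blood > 0, k_mr_tissue > 0,
            kappa > 0, kappa <= 1, smoothing_sigma_vox >= 0)
  structure(list(k_ct = k_ct, k_mr = k_mr, k_mr_blood = k_mr_blood,
                 k_mr_tissue = k_mr_tissue, kappa = kappa,
                 apply_hct = apply_hct,
                 smoothing_sigma_vox = smoothing_sigma_vox),
            class = "conversion_config")
}

# reshape 4D (x,y,z,t) to voxels x frames and back
as_voxel_matrix <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
}

#' CT attenuation to concentration
#'
#' Per voxel, the baseline attenuation `mu0` is the mean of the first B
#' frames; the concentration is `c(t_j) = k_ct * (mu(t_{j+B-1}) - mu0)`.
#' The first B - 1 frames are consumed: the output has `n - B + 1` samples
#' and t = 0 sits at the last baseline frame, where c = 0 by construction.
#' Note that with B = 1 the first concentration sample is exactly zero,
#' which makes the downstream Toeplitz system matrix rank deficient.
#'
#' @param series A CT [acquisition_series()].
#' @param cfg A [conversion_config()].
#' @return List with `conc` (4D array, x,y,z,(n-B+1)), `baseline` (3D mu0
#'   map), `grid` (the output [time_grid()]).
#' @export
ct_to_concentration <- function(series, cfg = conversion_config()) {
  stopifnot(inherits(series, "acquisition_series"))
  if (series$modality != "CT") stop("series modality is not CT")
  B <- series$baseline_frames
  d <- dim(series$data)
  V <- as_voxel_matrix(series$data)
  mu0 <- rowMeans(V[, seq_len(B), drop = FALSE])
  keep <- seq.int(B, d[4])
  conc <- cfg$k_ct * (V[, keep, drop = FALSE] - mu0)
  out_dim <- c(d[1:3], length(keep))
  list(conc = array(conc, out_dim),
       baseline = array(mu0, d[1:3]),
       grid = time_grid(series$grid$dt, length(keep)))
}

#' MR signal to concentration
#'
#' Per voxel, `s0` is the mean of the first B baseline frames and
#' `c(t_j) = -(k_mr / TE) * ln(s(t_{j+B-1}) / s0)` — the exact inverse of
#' the T2*-susceptibility signal model `s = s0 * exp(-TE * c / k_mr)`.
#' Voxels with non-positive signal anywhere in the series are flagged
#' invalid (their curves become `NA`) rather than clamped.
#'
#' @param series An MR [acquisition_series()].
#' @param cfg A [conversion_config()] (`k_mr_tissue` is used).
#' @return List with `conc`, `baseline` (s0 map), `grid`, and `invalid`
#'   (3D logical map of excluded voxels).
#' @export
mr_to_concentration <- function(series, cfg = conversion_config()) {
  stopifnot(inherits(series, "acquisition_series"))
  if (series$modality != "MR") stop("series modality is not MR")
  B <- series$baseline_frames
  d <- dim(series$data)
  V <- as_voxel_matrix(series$data)
  invalid <- apply(V <= 0, 1L, any)
  s0 <- rowMeans(V[, seq_len(B), drop = FALSE])
  keep <- seq.int(B, d[4])
  conc <- -(cfg$k_mr_tissue / series$te) * log(V[, keep, drop = FALSE] / s0)
  conc[invalid, ] <- NA_real_
  out_dim <- c(d[1:3], length(keep))
  list(conc = array(conc, out_dim),
       baseline = array(s0, d[1:3]),
       grid = time_grid(series$grid$dt, length(keep)),
       invalid = array(invalid, d[1:3]))
}

#' Hematocrit correction
#'
#' Multiplies a tissue time-concentration curve by kappa to compensate the
#' arterial-versus-capillary difference in plasma fraction. Arterial and
#' venous curves pass through unchanged.
#'
#' @param curve A [concentration_curve()].
#' @param cfg A [conversion_config()].
#' @return The (possibly scaled) curve.
#' @export
hematocrit_correct <- function(curve, cfg = conversion_config()) {
  stopifnot(inherits(curve, "concentration_curve"))
  if (curve$label != "tissue" || !cfg$apply_hct) return(curve)
  concentration_curve(curve$grid, cfg$kappa * curve$values, curve$label)
}

#' Bolus arrival time detection
#'
#' BAT is the interval between the start of scanning and the time the
#' curve begins to rise. Detected as the first sample t_j such that m
#' consecutive samples from t_j all exceed `z * noise_sd`. With
#' `noise_sd = 0` the threshold degenerates to "strictly positive".
#'
#' @param curve A [concentration_curve()].
#' @param noise_sd Baseline noise standard deviation (>= 0); estimate it
#'   from the converted baseline frames when available.
#' @param z Threshold multiplier (default 3).
#' @param m Number of consecutive supra-threshold samples required
#'   (default 2).
#' @return BAT in seconds (grid-aligned); `NA` when the threshold is never
#'   exceeded.
#' @export
detect_bat <- function(curve, noise_sd = 0, z = 3, m = 2L) {
  stopifnot(inherits(curve, "concentration_curve"), noise_sd >= 0)
  v <- curve$values
  n <- length(v)
  m <- as.integer(m)
  thr <- z * noise_sd
  above <- v > thr
  for (j in seq_len(n - m + 1L)) {
    if (all(above[j:(j + m - 1L)])) return((j - 1L) * curve$grid$dt)
  }
  NA_real_
}

# 1D Gaussian convolution matrix with zero padding (truncated at 3 sigma)
gauss_conv_matrix <- function(n, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  x <- seq.int(-radius, radius)
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + x
    ok <- j >= 1L & j <= n
    M[i, j[ok]] <- kern[ok]
  }
  M
}

#' Per-frame isotropic Gaussian smoothing
#'
#' Smooths every time frame independently with a separable isotropic
#' Gaussian kernel (truncated at 3 sigma, zero-padded at the boundary).
#' `sigma = 0` returns the input unchanged. Away from the volume boundary
#' the per-frame sum is conserved (the kernel is normalized).
#'
#' @param arr 4D array (x, y, z, frame).
#' @param sigma_vox Gaussian sigma in voxel units (>= 0).
#' @return Smoothed 4D array of the same shape.
#' @export
spatial_smooth <- function(arr, sigma_vox) {
  stopifnot(is.array(arr), length(dim(arr)) == 4L, sigma_vox >= 0)
  if (sigma_vox == 0) return(arr)
  d <- dim(arr)
  Ms <- lapply(d[1:3], gauss_conv_matrix, sigma = sigma_vox)
  out <- arr
  for (f in seq_len(d[4])) {
    vol <- out[, , , f, drop = FALSE]
    dim(vol) <- d[1:3]
    # dim 1
    vol <- array(Ms[[1]] %*% matrix(vol, d[1]), d[1:3])
    # dim 2
    vol <- aperm(array(Ms[[2]] %*% matrix(aperm(vol, c(2, 1, 3)), d[2]),
                       c(d[2], d[1], d[3])), c(2, 1, 3))
    # dim 3
    vol <- aperm(array(Ms[[3]] %*% matrix(aperm(vol, c(3, 1, 2)), d[3]),
                       c(d[3], d[1], d[2])), c(2, 3, 1))
    out[, , , f] <- vol
  }
  out
}

#' Threshold-based tissue mask
#'
#' Masks voxels whose baseline mean lies inside `[lo, hi]`. The CT defaults
#' (0 to 100 HU) retain brain parenchyma while excluding air, bone and
#' calcifications.
#'
#' @param series An [acquisition_series()].
#' @param lo,hi Baseline-mean bounds (CT: HU).
#' @return 3D logical array.
#' @export
tissue_mask <- function(series, lo = 0, hi = 100) {
  stopifnot(inherits(series, "acquisition_series"), lo < hi)
  B <- series$baseline_frames
  d <- dim(series$data)
  mu0 <- rowMeans(as_voxel_matrix(series$data)[, seq_len(B), drop = FALSE])
  mask <- array(mu0 >= lo & mu0 <= hi, d[1:3])
  if (!any(mask)) stop("no tissue voxels in [", lo, ", ", hi, "]")
  mask
}

#' Automated AIF selection
#'
#' Heuristic global-AIF detector: candidate voxels combine a very high peak
#' concentration (top percentile of c_max among masked voxels) with an
#' early bolus arrival (BAT at or below the masked median). The AIF is the
#' mean curve over the selected voxels. The procedure is deterministic. An
#' error is raised when no voxel stands out (uniform volumes) or fewer than
#' 50 voxels are masked.
#'
#' @param conc 4D concentration array.
#' @param mask 3D logical array.
#' @param grid [time_grid()] of the 4th dimension.
#' @param cmax_quantile Peak-height quantile defining candidates
#'   (default 0.99).
#' @param noise_sd Noise level for the BAT detector.
#' @return List with `aif` (arterial `concentration_curve`) and `voxels`
#'   (linear indices of the selected voxels).
#' @export
auto_aif <- function(conc, mask, grid, cmax_quantile = 0.99, noise_sd = 0) {
  stopifnot(length(dim(conc)) == 4L, is.logical(mask),
            inherits(grid, "time_grid"))
  vox <- which(mask)
  if (length(vox) < 50L) stop("auto_aif needs at least 50 masked voxels")
  Cmat <- matrix(aperm(conc, c(4, 1, 2, 3)), nrow = grid$n)[, vox,
                                                            drop = FALSE]
  cmax <- apply(Cmat, 2L, max)
  # vessel candidates: top percentile of peak height, widened to half the
  # global maximum so a partial-volume-attenuated artery is not shadowed
  # by a brighter vein (the arrival-time filter below separates the two)
  thr_peak <- min(stats::quantile(cmax, cmax_quantile, names = FALSE),
                  0.5 * max(cmax))
  if (thr_peak <= 2 * stats::median(cmax) || thr_peak <= 0)
    stop("no distinguishable arterial voxels; provide the AIF manually")
  cand <- which(cmax >= thr_peak)
  bat <- vapply(seq_along(vox), function(j)
    detect_bat(concentration_curve(grid, Cmat[, j], "tissue"),
               noise_sd = noise_sd), numeric(1))
  med_bat <- stats::median(bat, na.rm = TRUE)
  sel <- cand[!is.na(bat[cand]) & bat[cand] <= med_bat]
  if (!length(sel))
    stop("no candidate voxel has an early bolus arrival; provide the AIF manually")
  vals <- if (length(sel) == 1L) Cmat[, sel] else rowMeans(Cmat[, sel])
  list(aif = concentration_curve(grid, vals, label = "arterial"),
       voxels = vox[sel])
}

#' Partial-volume rescaling of the AIF
#'
#' An AIF measured in a vessel that only partially fills its voxel is
#' attenuated by an unknown positive factor. Because a large draining vein
#' carries the same total tracer mass, rescaling the AIF so its area
#' matches the venous-output area removes the attenuation:
#' `aif * AUC(vof) / AUC(aif)` (trapezoid areas).
#'
#' @param aif Arterial [concentration_curve()].
#' @param vof Venous [concentration_curve()] on the same grid.
#' @return The rescaled arterial curve.
#' @export
pvc_rescale_aif <- function(aif, vof) {
  stopifnot(inherits(aif, "concentration_curve"),
            inherits(vof, "concentration_curve"))
  if (!same_grid(aif$grid, vof$grid))
    stop("aif and vof are on different time grids")
  a <- curve_auc(aif)
  if (a <= 0) stop("AIF has non-positive area; cannot rescale")
  concentration_curve(aif$grid, aif$values * curve_auc(vof) / a,
                      label = "arterial")
}

#' Remove corrupted frames and regrid
#'
#' Frames with severe reconstruction artifacts are removed; interior gaps
#' are filled by linear interpolation back onto the original uniform grid
#' (the deconvolution requires uniform sampling). Dropped frames at either
#' end truncate the series instead of extrapolating.
#'
#' @param series An [acquisition_series()].
#' @param bad_frames Integer indices of frames to remove.
#' @return A new `acquisition_series` on a uniform grid.
#' @export
drop_frames <- function(series, bad_frames) {
  stopifnot(inherits(series, "acquisition_series"))
  bad_frames <- sort(unique(as.integer(bad_frames)))
  d <- dim(series$data)
  if (!length(bad_frames)) return(series)
  if (any(bad_frames < 1L | bad_frames > d[4]))
    stop("bad frame index out of range")
  keep <- setdiff(seq_len(d[4]), bad_frames)
  if (length(keep) < 4L) stop("fewer than 4 frames would remain")
  # truncate ends that were dropped
  out_idx <- seq.int(min(keep), max(keep))
  tt <- (seq_len(d[4]) - 1) * series$grid$dt
  V <- as_voxel_matrix(series$data)[, keep, drop = FALSE]
  # shared interpolation weights: out frame -> linear combo of kept frames
  W <- matrix(0, length(out_idx), length(keep))
  tk <- tt[keep]
  for (i in seq_along(out_idx)) {
    t_i <- tt[out_idx[i]]
    j <- findInterval(t_i, tk)
    if (tk[j] == t_i) W[i, j] <- 1
    else {
      w <- (t_i - tk[j]) / (tk[j + 1L] - tk[j])
      W[i, j] <- 1 - w; W[i, j + 1L] <- w
    }
  }
  newdata <- array(V %*% t(W), c(d[1:3], length(out_idx)))
  # baseline frames remaining after a possible front truncation
  B <- max(1L, series$baseline_frames - (min(keep) - 1L))
  B <- min(B, length(out_idx) - 1L)
  acquisition_series(newdata, series$modality, series$grid$dt, B,
                     te = series$te)
}
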