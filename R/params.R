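#' Cerebral blood flow from a flow-scaled residue
#'
#' `CBF = max(k) / rho_voi`, converted from 1/s to the clinical unit
#' mL/100 g/min (factor 100 * 60). The maximum — rather than k(0) — is used
#' because bolus delay can make k vanish at t = 0; a delayed k therefore
#' yields the same CBF as an undelayed one. On plateaus the first index
#' attaining the maximum is the one reported by [tmax_of_k()].
#'
#' @param k A `flow_scaled_residue`.
#' @param rho Mean tissue density rho_voi in g/mL (default 1.04).
#' @return CBF in mL/100 g/min; `NA` when `max(k) <= 0`.
#' @export
cbf_from_k <- function(k, rho = 1.04) {
  stopifnot(inherits(k, "flow_scaled_residue"))
  m <- max(k$values)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  m / rho * CBF_UNIT
}

#' Cerebral blood volume from a flow-scaled residue
#'
#' `CBV = (1/rho_voi) * integral of k` in mL/100 g (factor 100). The
#' integral uses the trapezoid rule; by default, negative samples (a
#' regularization artifact) are clipped to zero before integrating. A
#' warning is issued when k has not decayed near zero by the grid end, in
#' which case the truncated integral underestimates CBV.
#'
#' @inheritParams cbf_from_k
#' @param clip_negative Clip negative k samples before integrating.
#' @return CBV in mL/100 g; `NA` if the integral is negative.
#' @export
cbv_from_k <- function(k, rho = 1.04, clip_negative = TRUE) {
  stopifnot(inherits(k, "flow_scaled_residue"))
  v <- k$values
  m <- max(v)
  if (m > 0 && v[length(v)] > 0.05 * m)
    warning("k not decayed at grid end; CBV underestimated")
  if (clip_negative) v <- pmax(v, 0)
  integral <- pracma::trapz(grid_times(k$grid), v)
  if (!is.finite(integral) || integral < 0) return(NA_real_)
  integral / rho * 100
}

#' Mean transit time from a flow-scaled residue
#'
#' `MTT = integral of k / max(k)` in seconds — the central volume theorem
#' applied to k (the density rho and flow scale cancel between numerator
#' and denominator).
#'
#' @inheritParams cbv_from_k
#' @return MTT in s; `NA` when `max(k) <= 0`.
#' @export
mtt_from_k <- function(k, clip_negative = TRUE) {
  stopifnot(inherits(k, "flow_scaled_residue"))
  v <- k$values
  m <- max(v)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  if (clip_negative) v <- pmax(v, 0)
  pracma::trapz(grid_times(k$grid), v) / m
}

#' Time-to-maximum of the flow-scaled residue
#'
#' `TMAX = argmax_t k(t)`: the time of the (first) maximum of k. TMAX grows
#' with bolus delay and dispersion and is widely used as a stroke triage
#' parameter.
#'
#' @inheritParams cbf_from_k
#' @return TMAX in s; `NA` when `max(k) <= 0`.
#' @export
tmax_of_k <- function(k) {
  stopifnot(inherits(k, "flow_scaled_residue"))
  if (max(k$values) <= 0) return(NA_real_)
  grid_times(k$grid)[which.max(k$values)]
}

#' Curve-based perfusion parameters
#'
#' Parameters read directly off the tissue time-concentration curve, no
#' deconvolution involved: time-to-peak (TTP, time of the first maximum),
#' peak concentration c_max, first moment
#' `FM = integral(c * t) / integral(c)` (the centroid of the area under the
#' curve projected onto the time axis), and bolus arrival time (BAT) via
#' [detect_bat()].
#'
#' @param c_voi Tissue [concentration_curve()].
#' @param noise_sd Baseline noise standard deviation handed to the BAT
#'   detector.
#' @param z,m BAT detector parameters, see [detect_bat()].
#' @return List with `ttp`, `c_max`, `fm`, `bat` (seconds /
#'   concentration); `fm` is `NA` when the curve area is not positive.
#' @export
curve_params <- function(c_voi, noise_sd = 0, z = 3, m = 2L) {
  stopifnot(inherits(c_voi, "concentration_curve"))
  tt <- grid_times(c_voi$grid)
  v <- c_voi$values
  auc <- pracma::trapz(tt, v)
  fm <- if (auc > 0) pracma::trapz(tt, tt * v) / auc else NA_real_
  list(ttp = tt[which.max(v)],
       c_max = max(v),
       fm = fm,
       bat = detect_bat(c_voi, noise_sd = noise_sd, z = z, m = m))
}

#' Maximum slope CBF estimate
#'
#' Nondeconvolution CBF: under the no-venous-outflow assumption (observation
#' shorter than the transit time), the tissue curve is the running integral
#' of the AIF scaled by rho * CBF, so
#' `CBF = max(dc_voi/dt) / (rho * max(c_art))`. The derivative uses central
#' differences after an optional width-3 moving average. When outflow is
#' not negligible (realistic MTT), this estimator underestimates the
#' deconvolution CBF.
#'
#' @param c_voi Tissue [concentration_curve()].
#' @param c_art Arterial [concentration_curve()] on the same grid.
#' @param rho Tissue density g/mL.
#' @param smooth Apply the width-3 moving average before differentiating.
#' @return CBF in mL/100 g/min.
#' @export
max_slope_cbf <- function(c_voi, c_art, rho = 1.04, smooth = TRUE) {
  stopifnot(inherits(c_voi, "concentration_curve"),
            inherits(c_art, "concentration_curve"))
  if (!same_grid(c_voi$grid, c_art$grid))
    stop("curves are on different time grids")
  if (max(c_art$values) <= 0) stop("arterial curve has no positive peak")
  v <- c_voi$values
  if (smooth && length(v) >= 3L) {
    sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
    v[2:(length(v) - 1L)] <- sm[2:(length(v) - 1L)]
  }
  slope <- max(pracma::gradient(v, c_voi$grid$dt))
  slope / (rho * max(c_art$values)) * CBF_UNIT
}

#' AUC-ratio CBV estimate
#'
#' Nondeconvolution CBV from conservation of mass:
#' `CBV = (1/rho) * AUC(c_voi) / AUC(c_ref)`, where the reference curve is
#' either the arterial input or (equivalently, for fully decayed curves)
#' the venous outflow. Reported in mL/100 g.
#'
#' @param c_voi Tissue [concentration_curve()].
#' @param c_ref Arterial or venous reference [concentration_curve()].
#' @param rho Tissue density g/mL.
#' @return CBV in mL/100 g.
#' @export
cbv_auc_ratio <- function(c_voi, c_ref, rho = 1.04) {
  stopifnot(inherits(c_voi, "concentration_curve"),
            inherits(c_ref, "concentration_curve"))
  ref_auc <- curve_auc(c_ref)
  if (ref_auc <= 0) stop("reference curve has non-positive area")
  curve_auc(c_voi) / ref_auc / rho * 100
}

#' Peak-ratio blood-volume approximation
#'
#' `CBV ~ max(c_voi) / max(c_ven)`: a coarse, integral-free approximation
#' to the blood-volume fraction that only uses the curve maxima. The result
#' is a dimensionless mL/mL-style fraction, not unit-matched to
#' [cbv_auc_ratio()]; treat it as a qualitative screening value.
#'
#' @param c_voi Tissue [concentration_curve()].
#' @param c_ven Venous [concentration_curve()].
#' @return Dimensionless ratio of maxima.
#' @export
cbv_peak_ratio <- function(c_voi, c_ven) {
  stopifnot(inherits(c_voi, "concentration_curve"),
            inherits(c_ven, "concentration_curve"))
  if (max(c_ven$values) <= 0) stop("venous curve has no positive peak")
  max(c_voi$values) / max(c_ven$values)
}

new_parameter_map <- function(name, values, units, mask, provenance) {
  structure(list(name = name, values = values, units = units, mask = mask,
                 provenance = provenance),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  inside <- x$values[x$mask]
  cat(sprintf("parameter_map '%s' [%s]: %s voxels, median %.4g\n",
              x$name, x$units, sum(x$mask),
              stats::median(inside, na.rm = TRUE)))
  invisible(x)
}

#' Voxelwise perfusion parameter maps
#'
#' Applies the chosen deconvolution to every masked voxel of a 4D
#' concentration array and extracts the full parameter set. The system
#' matrix and its filtered pseudo-inverse are built once from the AIF and
#' applied to all voxel curves in one matrix product, so the per-voxel cost
#' is O(N^2). Invalid voxels (non-positive max k, non-finite curves)
#' propagate as `NA` into the maps and are counted in the provenance.
#'
#' @param conc 4D array (x, y, z, time) of concentrations.
#' @param aif Arterial [concentration_curve()] whose grid matches the 4th
#'   dimension.
#' @param mask 3D logical array selecting voxels to process.
#' @param spec A [regularization_spec()] (`selection` must be `"fixed"`;
#'   per-voxel adaptive selection is applied with [regularized_solution()]
#'   curve by curve if needed).
#' @param matrix_kind `"toeplitz"` or `"circulant"`.
#' @param rho Tissue density g/mL.
#' @param noise_sd Noise level handed to the BAT detector.
#' @return Named list of `parameter_map` objects: `cbf`, `cbv`, `mtt`,
#'   `tmax`, `ttp`, `fm`, `cmax`, `bat`.
#' @export
map_volume <- function(conc, aif, mask, spec = regularization_spec(),
                       matrix_kind = c("toeplitz", "circulant"),
                       rho = 1.04, noise_sd = 0) {
  matrix_kind <- match.arg(matrix_kind)
  stopifnot(length(dim(conc)) == 4L, is.logical(mask),
            all(dim(mask) == dim(conc)[1:3]),
            inherits(aif, "concentration_curve"))
  if (!any(mask)) stop("empty mask")
  N <- aif$grid$n
  if (dim(conc)[4] != N) stop("4th dimension of conc does not match AIF grid")
  if (spec$selection != "fixed")
    stop("map_volume uses a fixed lambda_rel; resolve the selection on a ",
         "representative curve first")
  A <- build_system_matrix(aif, matrix_kind)
  f <- filter_factors(A, spec$method, spec$lambda_rel)
  sv <- A$svd
  r <- sv$rank
  # filtered pseudo-inverse, applied to all voxel curves at once
  Ainv <- sv$v[, seq_len(r), drop = FALSE] %*%
    ((f / sv$d[seq_len(r)]) * t(sv$u[, seq_len(r), drop = FALSE]))
  vox <- which(mask)
  Cmat <- matrix(aperm(conc, c(4, 1, 2, 3)), nrow = N)[, vox, drop = FALSE]
  if (A$kind == "circulant")
    Cmat <- rbind(Cmat, matrix(0, N, ncol(Cmat)))
  Kmat <- (Ainv %*% Cmat)[seq_len(N), , drop = FALSE]
  tt <- grid_times(aif$grid)
  dims <- dim(mask)
  blank <- function() array(NA_real_, dims)
  maps <- list(cbf = blank(), cbv = blank(), mtt = blank(), tmax = blank(),
               ttp = blank(), fm = blank(), cmax = blank(), bat = blank())
  n_invalid <- 0L
  for (j in seq_along(vox)) {
    kv <- Kmat[, j]
    cv <- Cmat[seq_len(N), j]
    if (!all(is.finite(kv)) || !all(is.finite(cv))) {
      n_invalid <- n_invalid + 1L
      next
    }
    k <- new_flow_scaled_residue(aif$grid, kv)
    cbf <- cbf_from_k(k, rho)
    if (is.na(cbf)) n_invalid <- n_invalid + 1L
    cc <- concentration_curve(aif$grid, cv, "tissue")
    cp <- curve_params(cc, noise_sd = noise_sd)
    v <- vox[j]
    maps$cbf[v] <- cbf
    maps$cbv[v] <- suppressWarnings(cbv_from_k(k, rho))
    maps$mtt[v] <- mtt_from_k(k)
    maps$tmax[v] <- tmax_of_k(k)
    maps$ttp[v] <- cp$ttp
    maps$fm[v] <- cp$fm
    maps$cmax[v] <- cp$c_max
    maps$bat[v] <- cp$bat
  }
  units <- c(cbf = "mL/100g/min", cbv = "mL/100g", mtt = "s", tmax = "s",
             ttp = "s", fm = "s", cmax = "concentration", bat = "s")
  prov <- list(method = spec$method, lambda_rel = spec$lambda_rel,
               matrix_kind = matrix_kind, rho = rho,
               n_voxels = length(vox), n_invalid = n_invalid)
  out <- lapply(names(maps), function(nm)
    new_parameter_map(nm, maps[[nm]], units[[nm]], mask, prov))
  names(out) <- names(maps)
  out
}
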