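#' Gamma-variate arterial input specification
#'
#' The synthetic bolus model `c_art(t) = A * (t - t0)^alpha *
#' exp(-(t - t0)/beta)` for `t > t0`, 0 before onset — the standard
#' parametric shape of a first-pass contrast bolus. The peak sits at
#' `t0 + alpha * beta` and the analytic area is
#' `A * beta^(alpha+1) * Gamma(alpha+1)`.
#'
#' @param amplitude Scale A (concentration units).
#' @param onset Bolus onset t0 in seconds (>= 0).
#' @param alpha Shape (dimensionless, > 0).
#' @param beta Timescale in seconds (> 0).
#' @return An object of class `aif_spec`.
#' @export
aif_spec <- function(amplitude = 1, onset = 5, alpha = 3, beta = 1.5) {
  stopifnot(amplitude > 0, onset >= 0, alpha > 0, beta > 0)
  structure(list(amplitude = amplitude, onset = onset, alpha = alpha,
                 beta = beta),
            class = "aif_spec")
}

#' Amplitude giving a target peak concentration
#' @param spec An [aif_spec()] (its amplitude field is ignored).
#' @param peak Desired peak concentration.
#' @return The amplitude A such that `max(c_art) = peak`.
#' @export
aif_amplitude_for_peak <- function(spec, peak) {
  stopifnot(inherits(spec, "aif_spec"), peak > 0)
  tpk <- spec$alpha * spec$beta
  peak / (tpk^spec$alpha * exp(-spec$alpha))
}

#' Sample a gamma-variate AIF on a grid
#'
#' @param spec An [aif_spec()].
#' @param grid A [time_grid()].
#' @return Arterial [concentration_curve()].
#' @export
make_aif <- function(spec, grid) {
  stopifnot(inherits(spec, "aif_spec"), inherits(grid, "time_grid"))
  tt <- grid_times(grid)
  if (spec$onset >= tt[grid$n]) stop("AIF onset lies beyond the grid span")
  u <- pmax(tt - spec$onset, 0)
  vals <- spec$amplitude * u^spec$alpha * exp(-u / spec$beta)
  concentration_curve(grid, vals, label = "arterial")
}

#' Tissue curve from AIF and tissue kinetics
#'
#' The forward direction of the indicator-dilution model:
#' `c_voi = c_art * k` with `k = flow_scaled_residue(tk)`. The AUC ratio
#' `AUC(c_voi)/AUC(c_art)` equals `rho * CBV / 100` when both curves decay
#' within the grid.
#'
#' @param aif Arterial [concentration_curve()].
#' @param tk A [tissue_kinetics()].
#' @param grid A [time_grid()] (must match the AIF grid).
#' @return Tissue [concentration_curve()].
#' @export
make_tissue_curve <- function(aif, tk, grid = aif$grid) {
  stopifnot(inherits(aif, "concentration_curve"),
            inherits(tk, "tissue_kinetics"))
  if (!same_grid(aif$grid, grid))
    stop("aif and grid are inconsistent")
  forward_convolve(aif, flow_scaled_residue(tk, grid))
}

#' Phantom region
#'
#' @param kind `"tissue"` (carries [tissue_kinetics()]), `"artery"`,
#'   `"vein"` (carry the AIF / venous curve, optionally attenuated by a
#'   partial-volume factor), or `"static"` (no enhancement; e.g. air or
#'   bone, with its own baseline value).
#' @param tk [tissue_kinetics()] for tissue regions.
#' @param partial_volume Multiplicative attenuation of vessel curves in
#'   (0, 1].
#' @param baseline Region-specific baseline override (CT: HU); `NA` uses
#'   the phantom-wide baseline.
#' @return An object of class `phantom_region`.
#' @export
phantom_region <- function(kind = c("tissue", "artery", "vein", "static"),
                           tk = NULL, partial_volume = 1, baseline = NA) {
  kind <- match.arg(kind)
  if (kind == "tissue") stopifnot(inherits(tk, "tissue_kinetics"))
  stopifnot(partial_volume > 0, partial_volume <= 1)
  structure(list(kind = kind, tk = tk, partial_volume = partial_volume,
                 baseline = baseline),
            class = "phantom_region")
}

#' Digital perfusion phantom specification
#'
#' A full description of a synthetic 4D acquisition: spatial label array,
#' per-region kinetics or vessel role, bolus model, modality, noise and
#' baseline. Rendering it yields raw signal plus the complete ground truth,
#' so every processing stage can be validated without clinical data.
#'
#' @param labels 3D integer/character array of region labels.
#' @param regions Named list of [phantom_region()], one per label level.
#' @param aif An [aif_spec()].
#' @param grid [time_grid()] of the concentration curves (N samples).
#' @param modality `"CT"` or `"MR"`.
#' @param baseline Baseline level: HU for CT, s0 for MR.
#' @param baseline_frames Number of flat baseline frames B prepended.
#' @param noise_sd Noise standard deviation: HU for CT, fractional signal
#'   for MR. A seed is mandatory when `noise_sd > 0`.
#' @param te MR echo time in seconds.
#' @param venous_dist [transit_time_distribution()] of the whole-organ
#'   transit used to synthesize the venous outflow curve.
#' @param seed Integer RNG seed (required when `noise_sd > 0`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(labels, regions, aif, grid,
                         modality = c("CT", "MR"),
                         baseline = 35, baseline_frames = 4L,
                         noise_sd = 0, te = 0.03,
                         venous_dist = transit_time_distribution(
                           "gamma", shape = 4, scale = 1),
                         seed = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            inherits(aif, "aif_spec"), inherits(grid, "time_grid"),
            noise_sd >= 0)
  lev <- sort(unique(as.vector(labels)))
  if (!all(lev %in% names(regions)))
    stop("labels contain levels without a region definition: ",
         paste(setdiff(lev, names(regions)), collapse = ", "))
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is mandatory when noise_sd > 0")
  structure(list(labels = labels, regions = regions, aif = aif,
                 grid = grid, modality = modality, baseline = baseline,
                 baseline_frames = as.integer(baseline_frames),
                 noise_sd = noise_sd, te = te, venous_dist = venous_dist,
                 seed = seed),
            class = "phantom_spec")
}

# run expr with a locally seeded RNG, restoring global state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a phantom into a raw acquisition
#'
#' Builds the noiseless concentration curves per region (tissue curves via
#' the forward convolution, vessel curves from the bolus model scaled by
#' their partial-volume factor), prepends B flat baseline frames, and maps
#' concentrations into the native signal domain: CT
#' `signal = baseline + c/k_ct + N(0, noise_sd)`, MR
#' `signal = s0 * exp(-TE * c / k_mr) * (1 + N(0, noise_sd))`. Noise is
#' added in the signal domain, where scanner noise lives. Rendering is
#' fully deterministic given the seed. MR noise that would produce
#' non-positive signal is redrawn at half the standard deviation (with a
#' warning).
#'
#' @param spec A [phantom_spec()].
#' @param cfg A [conversion_config()] (k_ct / k_mr used in the forward
#'   signal model).
#' @return List with `series` ([acquisition_series()]) and `truth` — a
#'   list holding per-voxel `cbf`, `cbv`, `mtt`, `delay` maps, the region
#'   `labels`, the noiseless `aif`, `vof` and per-region curves, and the
#'   curve [time_grid()].
#' @export
render_acquisition <- function(spec, cfg = conversion_config()) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  N <- grid$n
  B <- spec$baseline_frames
  aif <- make_aif(spec$aif, grid)
  vof <- venous_outflow(aif, spec$venous_dist)
  dims <- dim(spec$labels)
  nvox <- prod(dims)
  curves <- matrix(0, nvox, N)
  base <- array(spec$baseline, dims)
  truth_maps <- list(cbf = array(NA_real_, dims), cbv = array(NA_real_, dims),
                     mtt = array(NA_real_, dims), delay = array(NA_real_, dims))
  region_curves <- list()
  for (nm in names(spec$regions)) {
    reg <- spec$regions[[nm]]
    sel <- which(spec$labels == nm)
    if (!length(sel)) next
    cv <- switch(reg$kind,
                 tissue = make_tissue_curve(aif, reg$tk, grid)$values,
                 artery = reg$partial_volume * aif$values,
                 vein = reg$partial_volume * vof$values,
                 static = rep(0, N))
    region_curves[[nm]] <- cv
    curves[sel, ] <- matrix(cv, length(sel), N, byrow = TRUE)
    if (!is.na(reg$baseline)) base[sel] <- reg$baseline
    if (reg$kind == "tissue") {
      truth_maps$cbf[sel] <- reg$tk$cbf
      truth_maps$cbv[sel] <- reg$tk$cbv
      truth_maps$mtt[sel] <- reg$tk$mtt
      truth_maps$delay[sel] <- reg$tk$delay
    }
  }
  # frames: B flat baseline frames, then curve samples 2..N
  # (frame B carries t = 0, where every curve is still at baseline)
  n_frames <- B + N - 1L
  sig <- matrix(0, nvox, n_frames)
  sig[, seq_len(B)] <- 0
  sig[, B + seq_len(N - 1L)] <- curves[, 2:N, drop = FALSE]
  if (spec$modality == "CT") {
    sig <- as.vector(base) + sig / cfg$k_ct
    if (spec$noise_sd > 0)
      sig <- sig + with_local_seed(spec$seed,
        matrix(stats::rnorm(length(sig), 0, spec$noise_sd), nrow(sig)))
  } else {
    sig <- as.vector(base) * exp(-spec$te * sig / cfg$k_mr_tissue)
    if (spec$noise_sd > 0) {
      eps <- with_local_seed(spec$seed,
        matrix(stats::rnorm(length(sig), 0, spec$noise_sd), nrow(sig)))
      bad <- sig * (1 + eps) <= 0
      if (any(bad)) {
        warning(sum(bad), " MR samples redrawn at half noise sd to stay positive")
        eps[bad] <- eps[bad] / 2
        while (any(sig * (1 + eps) <= 0)) eps[bad] <- eps[bad] / 2
      }
      sig <- sig * (1 + eps)
    }
  }
  series <- acquisition_series(array(sig, c(dims, n_frames)),
                               spec$modality, grid$dt, B,
                               te = if (spec$modality == "MR") spec$te)
  list(series = series,
       truth = c(truth_maps,
                 list(labels = spec$labels, aif = aif, vof = vof,
                      region_curves = region_curves, grid = grid)))
}

#' Reference digital perfusion phantom
#'
#' The canonical validation phantom: an 8 x 8 x 2 volume with grey matter
#' (CBF 60 mL/100 g/min, CBV 4 mL/100 g, MTT 4 s), white matter (CBF 25,
#' CBV 2, MTT 4.8 s), an ischemic lesion (CBF 15, CBV 3, MTT 12 s, 2 s
#' bolus delay, 1.5 s dispersion), one artery column and one vein column;
#' dt = 1 s, N = 40 samples, B = 4 baseline frames, CT modality with a
#' 35 HU tissue baseline and an arterial peak of 300 HU-equivalent
#' concentration. Grey/white values follow the standard physiologic ranges
#' for the healthy adult brain.
#'
#' @param noise_sd CT noise in HU (default 0).
#' @param seed RNG seed, required when `noise_sd > 0`.
#' @param aif_partial_volume Attenuation factor applied to the artery
#'   voxels (default 1 = none).
#' @return A [phantom_spec()].
#' @export
reference_phantom <- function(noise_sd = 0, seed = NULL,
                              aif_partial_volume = 1) {
  dims <- c(8L, 8L, 2L)
  labels <- array("grey", dims)
  labels[1:4, , ] <- "white"
  labels[5:6, 5:6, ] <- "lesion"
  labels[1, 1, ] <- "artery"
  labels[8, 8, ] <- "vein"
  regions <- list(
    grey = phantom_region("tissue", tissue_kinetics(cbf = 60, cbv = 4)),
    white = phantom_region("tissue", tissue_kinetics(cbf = 25, cbv = 2)),
    lesion = phantom_region("tissue",
                            tissue_kinetics(cbf = 15, cbv = 3, delay = 2,
                                            dispersion_tau = 1.5)),
    artery = phantom_region("artery", partial_volume = aif_partial_volume,
                            baseline = 45),
    vein = phantom_region("vein", baseline = 45))
  spec0 <- aif_spec(onset = 5, alpha = 3, beta = 1.5)
  spec0$amplitude <- aif_amplitude_for_peak(spec0, 300)
  phantom_spec(labels, regions, spec0, time_grid(1, 40),
               modality = "CT", baseline = 35, baseline_frames = 4L,
               noise_sd = noise_sd, seed = seed)
}
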