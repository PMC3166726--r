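#' Read a dynamic 4D NIfTI series
#'
#' The 4th NIfTI dimension is the time axis. The frame interval is taken
#' from the caller, not from the NIfTI header, whose time units are
#' unreliable in practice.
#'
#' @param path Path to a 4D NIfTI file.
#' @param modality `"CT"` or `"MR"`.
#' @param dt Frame interval in seconds.
#' @param baseline_frames Number of baseline frames B.
#' @param te MR echo time in seconds.
#' @return An [acquisition_series()].
#' @export
read_dynamic_nifti <- function(path, modality, dt, baseline_frames,
                               te = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI (x, y, z, time), got ",
         length(dim(arr)), "D: ", path)
  acquisition_series(arr, modality, dt, baseline_frames, te = te)
}

#' Read a 3D NIfTI mask
#'
#' @param path Path to a 3D NIfTI file (nonzero = masked in).
#' @return 3D logical array.
#' @export
read_mask_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI mask, got ", length(dim(arr)), "D: ", path)
  array(arr != 0, dim(arr))
}

#' Write parameter maps as NIfTI plus a JSON provenance sidecar
#'
#' One 3D NIfTI per map, named `<name>.nii.gz`, plus `provenance.json`
#' recording the deconvolution settings and voxel counts.
#'
#' @param maps Named list of `parameter_map` objects from [map_volume()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_parameter_maps <- function(maps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in maps) {
    p <- file.path(dir, paste0(m$name, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(m$values), p)
    paths <- c(paths, p)
  }
  prov <- maps[[1]]$provenance
  prov$units <- stats::setNames(lapply(maps, `[[`, "units"),
                                vapply(maps, `[[`, "", "name"))
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, pj))
}

#' Default run configuration
#'
#' All tunable pipeline settings with their shipped defaults: conversion
#' constants (`k_ct` 1 g/mL/HU, `k_mr` 1), hematocrit factor `kappa` 0.73,
#' tissue density `rho_voi` 1.04 g/mL, Tikhonov filtering on a Toeplitz
#' matrix with fixed `lambda_rel` 0.2, oscillation-index threshold 0.1,
#' 50-point lambda grid, CT mask bounds 0-100 HU, no smoothing.
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    modality = "CT", dt = 1, baseline_frames = 4L, te = 0.03,
    k_ct = 1, k_mr = 1, kappa = 0.73, apply_hct = TRUE, rho_voi = 1.04,
    matrix_kind = "toeplitz", filter = "tikhonov", lambda_rel = 0.2,
    selection = "fixed", oi_threshold = 0.1, lambda_grid = 50L,
    mask_lo = 0, mask_hi = 100, smoothing_sigma_vox = 0, seed = NULL),
    class = "run_config")
}

config_vocab <- list(modality = c("CT", "MR"),
                     matrix_kind = c("toeplitz", "circulant"),
                     filter = c("tikhonov", "tsvd"),
                     selection = c("fixed", "oi", "lcurve"))

validate_config <- function(cfg) {
  for (key in names(config_vocab)) {
    if (!cfg[[key]] %in% config_vocab[[key]])
      stop("config field '", key, "' must be one of: ",
           paste(config_vocab[[key]], collapse = ", "))
  }
  stopifnot(cfg$dt > 0, cfg$baseline_frames >= 1, cfg$k_ct > 0,
            cfg$k_mr > 0, cfg$kappa > 0, cfg$kappa <= 1, cfg$rho_voi > 0,
            cfg$lambda_rel > 0, cfg$lambda_rel <= 1,
            cfg$mask_lo < cfg$mask_hi, cfg$smoothing_sigma_vox >= 0)
  if (cfg$modality == "MR") stopifnot(cfg$te > 0)
  invisible(cfg)
}

#' Load a run configuration from JSON or YAML
#'
#' Keys present in the file override the built-in defaults; unknown keys
#' raise an error. The format is chosen by file extension (`.json`,
#' `.yaml`/`.yml`).
#'
#' @param path Config file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else stop("unsupported config format: .", ext)
  cfg <- default_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  cfg$baseline_frames <- as.integer(cfg$baseline_frames)
  validate_config(cfg)
  cfg
}

#' Save a run configuration as JSON
#' @param cfg A `run_config`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# content hash of an arbitrary R object (serialize + md5)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Run the full perfusion pipeline
#'
#' Chains convert -> (smooth, mask, AIF) -> deconvolve -> parameter maps on
#' an [acquisition_series()], and assembles a JSON-serializable report with
#' the effective configuration, provenance hashes, the selected
#' `lambda_rel`, Picard flag, oscillation-index summary, and per-voxel
#' failure counts. The AIF is auto-selected unless supplied.
#'
#' @param series An [acquisition_series()], e.g. from
#'   [read_dynamic_nifti()] or [render_acquisition()].
#' @param cfg A `run_config` from [default_config()] / [load_config()].
#' @param aif Optional arterial [concentration_curve()] overriding
#'   auto-selection.
#' @param vof Optional venous curve; when given, the AIF is
#'   partial-volume rescaled against it.
#' @return List with `maps` (see [map_volume()]), `aif`, and `report`.
#' @export
run_pipeline <- function(series, cfg = default_config(), aif = NULL,
                         vof = NULL) {
  stopifnot(inherits(series, "acquisition_series"))
  validate_config(cfg)
  ccfg <- conversion_config(k_ct = cfg$k_ct, k_mr = cfg$k_mr,
                            kappa = cfg$kappa, apply_hct = cfg$apply_hct,
                            smoothing_sigma_vox = cfg$smoothing_sigma_vox)
  input_hash <- object_hash(series$data)
  data <- series$data
  if (cfg$smoothing_sigma_vox > 0)
    data <- spatial_smooth(data, cfg$smoothing_sigma_vox)
  series <- acquisition_series(data, series$modality, series$grid$dt,
                               series$baseline_frames, te = series$te)
  mask <- if (series$modality == "CT")
    tissue_mask(series, cfg$mask_lo, cfg$mask_hi)
  else array(TRUE, dim(series$data)[1:3])
  conv <- if (series$modality == "CT") ct_to_concentration(series, ccfg)
  else mr_to_concentration(series, ccfg)
  if (!is.null(conv$invalid)) mask <- mask & !conv$invalid
  # baseline-noise estimate from the converted pre-bolus samples
  B <- series$baseline_frames
  noise_sd <- if (B >= 3L) {
    Vb <- as_voxel_matrix(series$data)[, seq_len(B), drop = FALSE]
    stats::median(apply(Vb - rowMeans(Vb), 1L, stats::sd)) * cfg$k_ct
  } else 0
  if (is.null(aif)) {
    # AIF search over everything above the mask floor, vessels included
    vessel_mask <- if (series$modality == "CT") {
      mu0 <- conv$baseline
      array(mu0 >= cfg$mask_lo, dim(mu0))
    } else mask
    sel <- auto_aif(conv$conc, vessel_mask, conv$grid, noise_sd = noise_sd)
    aif <- sel$aif
    aif_voxels <- sel$voxels
  } else aif_voxels <- NULL
  if (!is.null(vof)) aif <- pvc_rescale_aif(aif, vof)
  # hematocrit correction on tissue concentrations (linear => applied to
  # the 4D array directly)
  conc <- conv$conc
  if (cfg$apply_hct) conc <- conc * cfg$kappa
  spec <- regularization_spec(cfg$filter, lambda_rel = cfg$lambda_rel,
                              oi_threshold = cfg$oi_threshold,
                              lcurve_grid = cfg$lambda_grid)
  A <- build_system_matrix(aif, cfg$matrix_kind)
  lam_rel <- switch(cfg$selection,
                    fixed = cfg$lambda_rel,
                    oi = {
                      rep_curve <- representative_curve(conc, mask, conv$grid)
                      select_lambda_oi(A, rep_curve, spec)
                    },
                    lcurve = {
                      rep_curve <- representative_curve(conc, mask, conv$grid)
                      select_lambda_lcurve(A, rep_curve, spec)
                    })
  fixed_spec <- regularization_spec(cfg$filter, lambda_rel = lam_rel)
  maps <- map_volume(conc, aif, mask, fixed_spec,
                     matrix_kind = cfg$matrix_kind, rho = cfg$rho_voi,
                     noise_sd = noise_sd)
  rep_curve <- representative_curve(conc, mask, conv$grid)
  picard <- picard_diagnostic(A, rep_curve)
  oi_vals <- maps_oi(conc, A, fixed_spec, mask)
  report <- list(
    config = unclass(cfg),
    config_hash = object_hash(unclass(cfg)),
    input_hash = input_hash,
    seed = cfg$seed,
    tool_version = as.character(utils::packageVersion("perfkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_frames = series$grid$n, n_samples = conv$grid$n,
    n_masked = sum(mask),
    n_invalid = maps[[1]]$provenance$n_invalid,
    noise_sd_estimate = noise_sd,
    lambda_rel_used = lam_rel,
    picard_violated = picard$violated,
    oi_summary = as.list(stats::quantile(oi_vals, c(0.05, 0.5, 0.95),
                                         na.rm = TRUE)),
    parameters = vapply(maps, `[[`, "", "name"))
  list(maps = maps, aif = aif, aif_voxels = aif_voxels, report = report)
}

# mean masked tissue curve, used for regularization selection / diagnostics
representative_curve <- function(conc, mask, grid) {
  Cmat <- matrix(aperm(conc, c(4, 1, 2, 3)), nrow = grid$n)[, which(mask),
                                                            drop = FALSE]
  Cmat <- Cmat[, colSums(!is.finite(Cmat)) == 0, drop = FALSE]
  concentration_curve(grid, rowMeans(Cmat), "tissue")
}

# per-voxel oscillation indices under a fixed spec (diagnostic summary)
maps_oi <- function(conc, A, spec, mask) {
  N <- A$N
  vox <- which(mask)
  Cmat <- matrix(aperm(conc, c(4, 1, 2, 3)), nrow = N)[, vox, drop = FALSE]
  f <- filter_factors(A, spec$method, spec$lambda_rel)
  sv <- A$svd
  r <- sv$rank
  Ainv <- sv$v[, seq_len(r), drop = FALSE] %*%
    ((f / sv$d[seq_len(r)]) * t(sv$u[, seq_len(r), drop = FALSE]))
  if (A$kind == "circulant")
    Cmat <- rbind(Cmat, matrix(0, N, ncol(Cmat)))
  Kmat <- (Ainv %*% Cmat)[seq_len(N), , drop = FALSE]
  apply(Kmat, 2L, function(kv) {
    if (!all(is.finite(kv)) || max(kv) <= 0) return(NA_real_)
    oscillation_index(kv)
  })
}

#' Write a pipeline report as JSON
#' @param report The `report` element of a [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
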