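#' Transit-time distribution h(t)
#'
#' The microcirculation model assumes a stationary probability density h(t)
#' of capillary transit times: a blood cell entering the capillary bed at
#' t = 0 leaves it after a random transit time with density h. Supported
#' families are the gamma distribution (shape alpha, scale theta, mean
#' alpha * theta), the exponential distribution (scale tau, mean tau), and a
#' tabulated density sampled on a [time_grid()] (normalized on construction).
#'
#' @param family One of `"gamma"`, `"exponential"`, `"tabulated"`.
#' @param shape Gamma shape parameter (dimensionless, > 0).
#' @param scale Scale parameter in seconds (> 0); gamma scale or exponential
#'   mean.
#' @param table Sampled density values (tabulated family only).
#' @param grid [time_grid()] carrying `table` (tabulated family only).
#' @return An object of class `transit_time_distribution`.
#' @examples
#' h <- transit_time_distribution("gamma", shape = 4, scale = 1) # mean 4 s
#' @export
transit_time_distribution <- function(family = c("gamma", "exponential",
                                                 "tabulated"),
                                      shape = NULL, scale = NULL,
                                      table = NULL, grid = NULL) {
  family <- match.arg(family)
  out <- list(family = family)
  if (family == "gamma") {
    stopifnot(is.numeric(shape), shape > 0, is.numeric(scale), scale > 0)
    out$shape <- shape; out$scale <- scale
  } else if (family == "exponential") {
    stopifnot(is.numeric(scale), scale > 0)
    out$scale <- scale
  } else {
    stopifnot(inherits(grid, "time_grid"), length(table) == grid$n)
    table <- as.numeric(table)
    if (any(table < 0)) stop("tabulated density must be non-negative")
    area <- pracma::trapz(grid_times(grid), table)
    if (area <= 0) stop("tabulated density has zero area")
    out$table <- table / area
    out$grid <- grid
  }
  structure(out, class = "transit_time_distribution")
}

#' Mean of a transit-time distribution
#' @param dist A [transit_time_distribution()].
#' @return Mean transit time in seconds.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "transit_time_distribution"))
  switch(dist$family,
         gamma = dist$shape * dist$scale,
         exponential = dist$scale,
         tabulated = {
           tt <- grid_times(dist$grid)
           pracma::trapz(tt, tt * dist$table)
         })
}

# density samples h(t_j) on an arbitrary grid
sample_density <- function(dist, grid) {
  tt <- grid_times(grid)
  switch(dist$family,
         gamma = stats::dgamma(tt, shape = dist$shape, scale = dist$scale),
         exponential = stats::dexp(tt, rate = 1 / dist$scale),
         tabulated = {
           if (!same_grid(dist$grid, grid))
             stats::approx(grid_times(dist$grid), dist$table, xout = tt,
                           yleft = 0, yright = 0)$y
           else dist$table
         })
}

# cumulative distribution H(t_j) on a grid
sample_cdf <- function(dist, grid) {
  tt <- grid_times(grid)
  switch(dist$family,
         gamma = stats::pgamma(tt, shape = dist$shape, scale = dist$scale),
         exponential = stats::pexp(tt, rate = 1 / dist$scale),
         tabulated = {
           h <- sample_density(dist, grid)
           pmin(pracma::cumtrapz(tt, h)[, 1], 1)
         })
}

#' Residue function from a transit-time distribution
#'
#' The residue function r(t) = 1 - integral of h from 0 to t quantifies the
#' fraction of an idealized instantaneous arterial bolus still inside the
#' tissue volume at time t. It decreases continuously from r(0) = 1 towards
#' 0 and is non-increasing. Closed-form survival functions are used for the
#' gamma and exponential families; a cumulative trapezoid is used for
#' tabulated densities.
#'
#' @param dist A [transit_time_distribution()].
#' @param grid A [time_grid()]. The grid must cover the bulk of the
#'   distribution's support: an error is raised if the density integrates to
#'   less than 0.5 over the grid span.
#' @return An object of class `residue_function` with fields `grid`,
#'   `values`.
#' @examples
#' r <- residue_from_distribution(
#'   transit_time_distribution("gamma", shape = 4, scale = 1),
#'   time_grid(0.01, 4001))
#' mtt_of_residue(r) # ~ 4 s
#' @export
residue_from_distribution <- function(dist, grid) {
  stopifnot(inherits(dist, "transit_time_distribution"),
            inherits(grid, "time_grid"))
  H <- sample_cdf(dist, grid)
  if (H[grid$n] < 0.5)
    stop("grid does not cover distribution support")
  r <- pmin(pmax(1 - H, 0), 1)
  # enforce monotonicity against floating-point jitter in cumulative sums
  r <- rev(cummax(rev(r)))
  structure(list(grid = grid, values = r), class = "residue_function")
}

#' Mean transit time of a residue function
#'
#' By integration by parts, MTT equals the area under the residue function:
#' MTT = integral of r(t) dt. Computed with the trapezoid rule over the
#' grid. If the residue has not decayed below 0.01 by the end of the grid
#' the integral is truncated and MTT is underestimated; a warning is issued.
#'
#' @param r A `residue_function`.
#' @return MTT in seconds.
#' @export
mtt_of_residue <- function(r) {
  stopifnot(inherits(r, "residue_function"))
  if (r$values[r$grid$n] > 0.01)
    warning("truncated residue; MTT underestimated")
  pracma::trapz(grid_times(r$grid), r$values)
}

#' Tissue kinetics of one compartment
#'
#' Ground-truth or estimated perfusion state of a tissue compartment.
#' Exactly two of CBF, CBV, MTT are free; the third follows from the central
#' volume theorem CBF = CBV / MTT (with CBF in mL/100 g/min, CBV in
#' mL/100 g and MTT in s, `cbf = 60 * cbv / mtt`).
#'
#' @param cbf Cerebral blood flow, mL/100 g/min.
#' @param cbv Cerebral blood volume, mL/100 g.
#' @param mtt Mean transit time, s.
#' @param rho_voi Mean tissue density, g/mL (default 1.04, standard brain
#'   tissue).
#' @param delay Bolus delay from the global AIF site to the tissue, s (>= 0).
#' @param dispersion_tau Time constant of the causal exponential dispersion
#'   kernel, s (0 = no dispersion).
#' @param residue_family `"gamma"` or `"exponential"` residue shape.
#' @param shape Gamma shape when `residue_family = "gamma"` (default 4).
#' @return An object of class `tissue_kinetics` with all three of
#'   cbf/cbv/mtt populated and consistent.
#' @examples
#' tissue_kinetics(cbv = 4, mtt = 4) # grey matter: CBF 60 mL/100 g/min
#' @export
tissue_kinetics <- function(cbf = NULL, cbv = NULL, mtt = NULL,
                            rho_voi = 1.04, delay = 0, dispersion_tau = 0,
                            residue_family = c("exponential", "gamma"),
                            shape = 4) {
  residue_family <- match.arg(residue_family)
  given <- !c(cbf = is.null(cbf), cbv = is.null(cbv), mtt = is.null(mtt))
  if (sum(given) < 2L)
    stop("provide at least two of cbf, cbv, mtt")
  if (is.null(cbf)) cbf <- 60 * cbv / mtt
  if (is.null(cbv)) cbv <- cbf * mtt / 60
  if (is.null(mtt)) mtt <- 60 * cbv / cbf
  if (abs(cbf - 60 * cbv / mtt) > 1e-9 * abs(cbf))
    stop("cbf, cbv, mtt violate the central volume theorem cbf = 60*cbv/mtt")
  stopifnot(cbf > 0, cbv > 0, mtt > 0, rho_voi > 0, delay >= 0,
            dispersion_tau >= 0)
  structure(list(cbf = cbf, cbv = cbv, mtt = mtt, rho_voi = rho_voi,
                 delay = delay, dispersion_tau = dispersion_tau,
                 residue_family = residue_family, shape = shape),
            class = "tissue_kinetics")
}

#' @export
print.tissue_kinetics <- function(x, ...) {
  cat(sprintf(
    "tissue_kinetics: CBF %.3g mL/100g/min, CBV %.3g mL/100g, MTT %.3g s\n",
    x$cbf, x$cbv, x$mtt))
  if (x$delay > 0 || x$dispersion_tau > 0)
    cat(sprintf("  delay %.3g s, dispersion tau %.3g s\n",
                x$delay, x$dispersion_tau))
  invisible(x)
}

# conversion mL/100g/min -> mL/(g s)
CBF_UNIT <- 100 * 60

new_flow_scaled_residue <- function(grid, values, diagnostics = list()) {
  structure(list(grid = grid, values = as.numeric(values),
                 diagnostics = diagnostics),
            class = "flow_scaled_residue")
}

#' @export
print.flow_scaled_residue <- function(x, ...) {
  cat(sprintf("flow_scaled_residue: n = %d, max(k) = %.4g 1/s at t = %g s\n",
              x$grid$n, max(x$values),
              grid_times(x$grid)[which.max(x$values)]))
  d <- x$diagnostics
  if (length(d))
    cat(sprintf("  lambda_rel %s, OI %.3g, |Ak-c| %.3g, |k| %.3g\n",
                format(d$lambda_rel_used), d$oscillation_index %||% NA,
                d$residual_norm %||% NA, d$solution_norm %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flow-scaled residue function k(t)
#'
#' Builds k(t) = CBF * rho_voi * r(t) (units 1/s), the quantity recovered by
#' deconvolution, from a tissue-kinetics description. The residue shape is
#' taken from `residue_family` scaled so that its mean equals MTT. A bolus
#' delay shifts k right by `round(delay/dt)` samples (zero-filled); bolus
#' dispersion convolves k with a normalized causal exponential kernel
#' `exp(-t/tau)/tau`, which lowers max(k) while conserving the area (hence
#' CBV) to within discretization error.
#'
#' @param tk A [tissue_kinetics()].
#' @param grid A [time_grid()].
#' @return A `flow_scaled_residue`.
#' @examples
#' k <- flow_scaled_residue(tissue_kinetics(cbf = 60, mtt = 4),
#'                          time_grid(1, 40))
#' max(k$values) # 60/(100*60) * 1.04 = 0.0104 1/s
#' @export
flow_scaled_residue <- function(tk, grid) {
  stopifnot(inherits(tk, "tissue_kinetics"), inherits(grid, "time_grid"))
  dist <- if (tk$residue_family == "gamma")
    transit_time_distribution("gamma", shape = tk$shape,
                              scale = tk$mtt / tk$shape)
  else
    transit_time_distribution("exponential", scale = tk$mtt)
  r <- residue_from_distribution(dist, grid)
  k <- (tk$cbf / CBF_UNIT) * tk$rho_voi * r$values
  if (tk$dispersion_tau > 0) {
    tt <- grid_times(grid)
    g <- exp(-tt / tk$dispersion_tau) / tk$dispersion_tau
    g <- g / (grid$dt * sum(g)) # unit rectangle-rule area
    k <- grid$dt * causal_convolve(g, k)
  }
  if (tk$delay > 0) {
    shift <- round(tk$delay / grid$dt)
    if (shift >= grid$n)
      stop("delay (", tk$delay, " s) meets or exceeds the grid span")
    if (shift > 0)
      k <- c(rep(0, shift), k[seq_len(grid$n - shift)])
  }
  new_flow_scaled_residue(grid, k)
}

# causal discrete convolution (rectangle rule without the dt factor):
# y_j = sum_{i=1..j} a_i b_{j-i+1}. Direct summation: exact zeros stay
# exact (FFT-based convolution would leave ~1e-14 jitter that corrupts
# onset detection downstream).
causal_convolve <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  y <- numeric(n)
  for (j in seq_len(n)) y[j] <- sum(a[seq_len(j)] * b[j:1])
  y
}

#' Forward convolution: tissue curve from AIF and k
#'
#' The discrete indicator-dilution forward model
#' `c_voi(t_j) = dt * sum_i c_art(t_i) * k(t_{j-i+1})` (rectangle rule,
#' causal: k indices below 1 contribute zero). This exact discretization is
#' what the Toeplitz system matrix inverts, so an impulse AIF of height
#' 1/dt reproduces k exactly.
#'
#' @param aif Arterial [concentration_curve()].
#' @param k A `flow_scaled_residue` on the same grid.
#' @return Tissue `concentration_curve`.
#' @export
forward_convolve <- function(aif, k) {
  stopifnot(inherits(aif, "concentration_curve"),
            inherits(k, "flow_scaled_residue"))
  if (!same_grid(aif$grid, k$grid))
    stop("aif and k are on different time grids")
  vals <- aif$grid$dt * causal_convolve(aif$values, k$values)
  concentration_curve(aif$grid, vals, label = "tissue")
}

#' Venous outflow curve
#'
#' The concentration at the venous outlet is the arterial input convolved
#' with the transit-time density: c_ven = c_art * h. Because h integrates
#' to one, the venous curve conserves the arterial area (mass conservation)
#' on grids covering both curves' support.
#'
#' @param aif Arterial [concentration_curve()].
#' @param dist A [transit_time_distribution()].
#' @return Venous `concentration_curve`.
#' @export
venous_outflow <- function(aif, dist) {
  stopifnot(inherits(aif, "concentration_curve"),
            inherits(dist, "transit_time_distribution"))
  h <- sample_density(dist, aif$grid)
  vals <- aif$grid$dt * causal_convolve(aif$values, h)
  concentration_curve(aif$grid, vals, label = "venous")
}
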