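#' Uniform time grid
#'
#' Dynamic perfusion series are sampled at discrete time points
#' `t_j = (j - 1) * dt`, `j = 1, ..., n`, with the origin fixed at `t = 0`.
#' All curves, residue functions and system matrices in this package live on
#' such a grid.
#'
#' @param dt Sampling period in seconds (> 0). A typical value for CT
#'   perfusion is 1 s.
#' @param n Number of samples (integer >= 2).
#' @return An object of class `time_grid` with fields `dt` and `n`.
#' @examples
#' g <- time_grid(dt = 1, n = 40)
#' head(grid_times(g))
#' @export
time_grid <- function(dt, n) {
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 2L)
  structure(list(dt = as.numeric(dt), n = n), class = "time_grid")
}

#' Sample times of a grid
#'
#' @param grid A [time_grid()].
#' @return Numeric vector `(0, dt, ..., (n-1) * dt)` in seconds.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  (seq_len(grid$n) - 1) * grid$dt
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$dt, b$dt)) && a$n == b$n
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: n = %d samples, dt = %g s, span = %g s\n",
              x$n, x$dt, (x$n - 1) * x$dt))
  invisible(x)
}

#' Time-concentration curve
#'
#' A uniformly sampled contrast-agent concentration series. CT concentrations
#' are in g/mL (after conversion from HU); MR concentrations are in
#' proportional units. Baseline-subtracted curves may contain small negative
#' values due to noise; these are allowed.
#'
#' @param grid A [time_grid()].
#' @param values Numeric vector of concentrations, one per grid sample.
#' @param label One of `"arterial"`, `"venous"`, `"tissue"`.
#' @return An object of class `concentration_curve`.
#' @export
concentration_curve <- function(grid, values,
                                label = c("tissue", "arterial", "venous")) {
  stopifnot(inherits(grid, "time_grid"))
  label <- match.arg(label)
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop("curve length (", length(values), ") does not match grid (n = ",
         grid$n, ")")
  if (!all(is.finite(values)))
    stop("curve contains non-finite values")
  structure(list(grid = grid, values = values, label = label),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("concentration_curve [%s]: n = %d, dt = %g s, peak = %.4g at t = %g s\n",
              x$label, x$grid$n, x$grid$dt,
              max(x$values), grid_times(x$grid)[which.max(x$values)]))
  invisible(x)
}

#' Trapezoidal area under a curve
#'
#' @param curve A [concentration_curve()] or numeric vector with `dt`.
#' @param dt Sampling period, only needed when `curve` is a bare vector.
#' @return Area in concentration * s.
#' @export
curve_auc <- function(curve, dt = NULL) {
  if (inherits(curve, "concentration_curve"))
    return(pracma::trapz(grid_times(curve$grid), curve$values))
  stopifnot(!is.null(dt))
  pracma::trapz((seq_along(curve) - 1) * dt, as.numeric(curve))
}

#' Read a time-concentration curve from CSV
#'
#' The CSV dialect has two columns `time_s,value` with a header row. Times
#' must be uniformly spaced starting at 0.
#'
#' @param path File path.
#' @param label Curve label, see [concentration_curve()].
#' @return A `concentration_curve`.
#' @export
read_curve_csv <- function(path, label = "tissue") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("curve CSV must have columns 'time_s' and 'value': ", path)
  tt <- df$time_s
  if (length(tt) < 2L) stop("curve CSV has fewer than 2 samples: ", path)
  dts <- diff(tt)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1])
    stop("curve CSV time column is not uniformly spaced: ", path)
  if (abs(tt[1]) > 1e-9)
    stop("curve CSV must start at time 0: ", path)
  concentration_curve(time_grid(dts[1], length(tt)), df$value, label = label)
}

#' Write a time-concentration curve to CSV
#'
#' @param curve A [concentration_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "concentration_curve"))
  utils::write.csv(
    data.frame(time_s = grid_times(curve$grid), value = curve$values),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
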