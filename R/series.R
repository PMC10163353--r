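#' Gridded velocity-field time series
#'
#' Container for planar PIV-style measurements: lateral and transverse
#' velocity components sampled on a uniform node-centered grid over a set of
#' uniformly spaced times, together with a validity mask that is `FALSE`
#' where vectors have been removed (typically inside the body contour).
#'
#' @param x,y strictly increasing, uniformly spaced grid coordinates
#' @param t strictly increasing, uniformly spaced sample times
#' @param u,v numeric arrays of dim `c(length(x), length(y), length(t))`
#' @param mask logical array of the same dim; `TRUE` marks valid vectors.
#'   `u`/`v` must be finite wherever `mask` is `TRUE`.
#' @param units `"nondimensional"` or `"dimensional"`
#' @return an object of class `"velocity_series"`
#' @export
velocity_series <- function(x, y, t, u, v, mask = NULL,
                            units = "nondimensional") {
  dims <- c(length(x), length(y), length(t))
  if (any(dims == 0)) stop("empty series")
  u <- check_field_array(u, dims, "u")
  v <- check_field_array(v, dims, "v")
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- check_field_array(mask, dims, "mask", logical = TRUE)
  check_uniform_axis(x, "x")
  check_uniform_axis(y, "y")
  check_uniform_axis(t, "times")
  if (any(!is.finite(u[mask])) || any(!is.finite(v[mask])))
    stop("non-finite velocity at a valid (unmasked) node")
  structure(list(x = as.numeric(x), y = as.numeric(y), t = as.numeric(t),
                 u = u, v = v, mask = mask),
            units = match.arg(units, c("nondimensional", "dimensional")),
            class = "velocity_series")
}

#' Gridded pressure-field time series
#'
#' Same axes as [velocity_series()]. Because the governing equations
#' constrain only pressure gradients, every pressure series carries an
#' explicit gauge declaration; comparing series with different gauges
#' without removing the gauge is an error.
#'
#' @inheritParams velocity_series
#' @param p numeric array of dim `c(length(x), length(y), length(t))`
#' @param gauge `"zero_mean"` (spatial mean over valid nodes is zero) or
#'   `"zero_at_boundary"` (referenced to zero at the external boundary)
#' @param mask validity mask as in [velocity_series()]
#' @return an object of class `"pressure_series"`
#' @export
pressure_series <- function(x, y, t, p, gauge = c("zero_mean", "zero_at_boundary"),
                            mask = NULL, units = "nondimensional") {
  gauge <- match.arg(gauge)
  dims <- c(length(x), length(y), length(t))
  if (any(dims == 0)) stop("empty series")
  p <- check_field_array(p, dims, "p")
  if (is.null(mask)) mask <- array(TRUE, dims)
  mask <- check_field_array(mask, dims, "mask", logical = TRUE)
  check_uniform_axis(x, "x")
  check_uniform_axis(y, "y")
  check_uniform_axis(t, "times")
  structure(list(x = as.numeric(x), y = as.numeric(y), t = as.numeric(t),
                 p = p, mask = mask, gauge = gauge),
            units = match.arg(units, c("nondimensional", "dimensional")),
            class = "pressure_series")
}

check_field_array <- function(a, dims, name, logical = FALSE) {
  if (length(dims) == 3 && is.matrix(a) && dims[3] == 1) a <- array(a, dims)
  if (!is.array(a) || !identical(dim(a), as.integer(dims)))
    stop(sprintf("'%s' must be an array of dim (%s)", name,
                 paste(dims, collapse = ", ")))
  if (logical && !is.logical(a)) stop(sprintf("'%s' must be logical", name))
  a
}

check_uniform_axis <- function(v, name, rtol = 1e-9) {
  if (length(v) == 1) return(invisible(v))
  d <- diff(v)
  if (any(d <= 0)) stop(sprintf("%s not increasing", name))
  if (length(d) > 1 && (max(d) - min(d)) > rtol * max(abs(d)))
    stop(sprintf("non-uniform %s spacing", name))
  invisible(v)
}

grid_step <- function(series) {
  c(dx = if (length(series$x) > 1) series$x[2] - series$x[1] else NA_real_,
    dy = if (length(series$y) > 1) series$y[2] - series$y[1] else NA_real_,
    dt = if (length(series$t) > 1) series$t[2] - series$t[1] else NA_real_)
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("Velocity series: %d x %d grid, %d time steps (%s)\n",
              length(x$x), length(x$y), length(x$t), attr(x, "units")))
  cat(sprintf("  x in [%g, %g], y in [%g, %g], t in [%g, %g]\n",
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$t), max(x$t)))
  cat(sprintf("  %d of %d nodes masked (body interior / removed vectors)\n",
              sum(!x$mask), length(x$mask)))
  invisible(x)
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf("Pressure series: %d x %d grid, %d time steps (%s, gauge %s)\n",
              length(x$x), length(x$y), length(x$t), attr(x, "units"), x$gauge))
  invisible(x)
}

#' Remove the pressure gauge from a series
#'
#' Subtracts the mean over all valid (and finite) nodes and times, yielding a
#' `zero_mean` gauge. Used before comparing reconstructions whose additive
#' constants are not pinned to the same reference.
#'
#' @param series a [pressure_series()]
#' @return the series with gauge `"zero_mean"`
#' @export
remove_gauge <- function(series) {
  stopifnot(inherits(series, "pressure_series"))
  ok <- series$mask & is.finite(series$p)
  series$p[ok] <- series$p[ok] - mean(series$p[ok])
  series$gauge <- "zero_mean"
  series
}

series_points <- function(series, valid_only = TRUE) {
  dims <- dim(series$mask)
  grid <- expand.grid(x = series$x, y = series$y, t = series$t,
                      KEEP.OUT.ATTRS = FALSE)
  keep <- if (valid_only) as.vector(series$mask) else rep(TRUE, nrow(grid))
  cbind(x = grid$x[keep], y = grid$y[keep], t = grid$t[keep])
}
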