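#' Characteristic scales for non-dimensionalization
#'
#' Bundles the characteristic length, time and velocity together with the
#' fluid density and kinematic viscosity. All internal computation in
#' pivpressure is performed in non-dimensional variables: coordinates are
#' divided by `L`, times by `T`, velocities by `U`. The Reynolds number is
#' `Re = U * L / nu`; for the undulatory-swimmer convention where the
#' characteristic velocity is the body length per tail-beat period
#' (`U = L * f`), this reduces to `Re = L^2 * f / nu`.
#'
#' @param L characteristic length (m, or 1 for already-nondimensional data)
#' @param T characteristic time (s)
#' @param U characteristic velocity; defaults to `L / T`
#' @param rho fluid density (kg/m^3)
#' @param nu kinematic viscosity (m^2/s); defaults to `U * L / Re`
#' @param Re Reynolds number; defaults to `U * L / nu`
#' @return an object of class `"scaling_set"`
#' @examples
#' scaling_set(L = 0.022, T = 0.15, Re = 918)
#' @export
scaling_set <- function(L = 1, T = 1, U = L / T, rho = 1, nu = NULL, Re = NULL) {
  if (!is.numeric(L) || L <= 0) stop("characteristic length must be positive")
  if (!is.numeric(T) || T <= 0) stop("characteristic time must be positive")
  if (!is.numeric(U) || U <= 0) stop("characteristic velocity must be positive")
  if (rho <= 0) stop("density must be positive")
  if (is.null(nu) && is.null(Re))
    stop("supply at least one of 'nu' or 'Re'")
  if (is.null(Re)) Re <- U * L / nu
  if (is.null(nu)) nu <- U * L / Re
  if (Re <= 0) stop("Reynolds number must be positive")
  if (abs(Re - U * L / nu) > 1e-6 * Re)
    stop("inconsistent scales: Re != U * L / nu")
  structure(list(L = L, T = T, U = U, rho = rho, nu = nu, Re = Re),
            class = "scaling_set")
}

#' @export
print.scaling_set <- function(x, ...) {
  cat("Characteristic scales: L =", x$L, " T =", x$T, " U =", x$U, "\n")
  cat("  rho =", x$rho, " nu =", signif(x$nu, 6), " Re =", signif(x$Re, 6), "\n")
  invisible(x)
}

is_dimensional <- function(series) isTRUE(attr(series, "units") == "dimensional")

#' Non-dimensionalize or re-dimensionalize a field series
#'
#' Applies `x/L`, `t/T`, `u/U` (and `p / (rho U^2)` for pressure series) so
#' that the Navier-Stokes residuals take their standard non-dimensional form
#' with the single parameter `Re`. `redimensionalize()` is the exact inverse.
#'
#' @param series a [velocity_series()] or [pressure_series()]
#' @param scaling a [scaling_set()]
#' @return a series of the same class in non-dimensional units
#' @export
nondimensionalize <- function(series, scaling) {
  stopifnot(inherits(scaling, "scaling_set"))
  if (!is_dimensional(series)) return(series)
  out <- series
  out$x <- series$x / scaling$L
  out$y <- series$y / scaling$L
  out$t <- series$t / scaling$T
  if (!is.null(series$u)) {
    out$u <- series$u / scaling$U
    out$v <- series$v / scaling$U
  }
  if (!is.null(series$p)) out$p <- series$p / (scaling$rho * scaling$U^2)
  attr(out, "units") <- "nondimensional"
  attr(out, "scaling") <- scaling
  out
}

#' @rdname nondimensionalize
#' @export
redimensionalize <- function(series, scaling = attr(series, "scaling")) {
  stopifnot(inherits(scaling, "scaling_set"))
  if (is_dimensional(series)) return(series)
  out <- series
  out$x <- series$x * scaling$L
  out$y <- series$y * scaling$L
  out$t <- series$t * scaling$T
  if (!is.null(series$u)) {
    out$u <- series$u * scaling$U
    out$v <- series$v * scaling$U
  }
  if (!is.null(series$p)) out$p <- series$p * (scaling$rho * scaling$U^2)
  attr(out, "units") <- "dimensional"
  attr(out, "scaling") <- scaling
  out
}
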