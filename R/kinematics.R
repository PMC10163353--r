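#' Body kinematics: moving closed contour with surface velocities
#'
#' Time series of a closed 2D body contour with outward unit normals, the
#' material velocity of each surface point, and the scalar normal velocity
#' `u_n = (u, v) . n` that enters the non-penetration boundary condition.
#'
#' @param times numeric vector of sample times
#' @param contours list (one element per time) of data frames with columns
#'   `x`, `y` (contour coordinates, ordered along the contour) and `u`, `v`
#'   (surface material velocity). Optional columns `station` (arc-projected
#'   axial position in body lengths, nose = 0) and `side` (`"left"`/`"right"`)
#'   are carried through to surface-pressure reports. Normals and `u_n` are
#'   computed here.
#' @return an object of class `"body_kinematics"`: the input with columns
#'   `nx`, `ny`, `un` added to every contour
#' @export
body_kinematics <- function(times, contours) {
  if (length(times) != length(contours))
    stop("one contour per time step required")
  check_uniform_axis(times, "times")
  contours <- lapply(contours, function(ct) {
    ct <- as.data.frame(ct)
    if (!all(c("x", "y", "u", "v") %in% names(ct)))
      stop("contour needs columns x, y, u, v")
    n <- nrow(ct)
    if (n < 3) stop("open or degenerate contour: need >= 3 points")
    if (abs(polygon_signed_area(ct$x, ct$y)) < 1e-14)
      stop("open contour: zero enclosed area")
    nr <- polygon_normals(ct$x, ct$y)
    ct$nx <- nr[, "nx"]; ct$ny <- nr[, "ny"]
    ct$un <- ct$u * ct$nx + ct$v * ct$ny
    ct
  })
  structure(list(times = as.numeric(times), contours = contours),
            class = "body_kinematics")
}

#' @export
print.body_kinematics <- function(x, ...) {
  cat(sprintf("Body kinematics: %d time steps, %d contour points\n",
              length(x$times), nrow(x$contours[[1]])))
  invisible(x)
}

contour_at <- function(kin, time, tol = 1e-8) {
  i <- which(abs(kin$times - time) <= tol + 1e-12 * max(abs(kin$times)))
  if (length(i) == 0)
    stop(sprintf("contour undefined at requested time %g", time))
  kin$contours[[i[1]]]
}

#' Parameters of the prescribed carangiform swimming motion
#'
#' The lateral displacement of the body midline is
#' `dy/L = A(x) * sin(k x - 2 pi f t + phi)` with quadratic amplitude
#' envelope `A(x) = a0 + a1 (x/L) + a2 (x/L)^2`. Defaults follow the
#' mackerel-style prescription: `a0 = 0.02`, `a1 = -0.08`, `a2 = 0.16`,
#' `k = 2 pi / L`, so the envelope grows from 0.02 L at the nose to 0.10 L
#' at the tail.
#'
#' @param a0,a1,a2 amplitude-envelope coefficients (body lengths)
#' @param L body length (nondimensional 1)
#' @param k undulation wave number, default `2 * pi / L`
#' @param f tail-beat frequency, default 1 (one period per time unit)
#' @param phi phase offset (rad)
#' @param halfwidth function of `x/L` in `[0, 1]` giving the local body
#'   half-width in body lengths; must vanish at nose and tail. The default is
#'   a smooth fish-like profile with maximum half-width 0.15 L.
#' @return an object of class `"carangiform_params"`
#' @export
carangiform_params <- function(a0 = 0.02, a1 = -0.08, a2 = 0.16, L = 1,
                               k = 2 * pi / L, f = 1, phi = 0,
                               halfwidth = NULL) {
  if (L <= 0 || f <= 0) stop("L and f must be positive")
  if (is.null(halfwidth))
    halfwidth <- function(s) 0.15 * sin(pi * pmin(pmax(s, 0), 1))^0.5
  stopifnot(is.function(halfwidth))
  structure(list(a0 = a0, a1 = a1, a2 = a2, L = L, k = k, f = f, phi = phi,
                 T_period = 1 / f, halfwidth = halfwidth),
            class = "carangiform_params")
}

#' Amplitude envelope of the carangiform motion
#' @param params a [carangiform_params()]
#' @param x axial coordinate (same units as `params$L`)
#' @return envelope `A(x)` in body lengths
#' @export
amplitude_envelope <- function(params, x) {
  s <- x / params$L
  params$a0 + params$a1 * s + params$a2 * s^2
}

midline_displacement <- function(params, x, t) {
  params$L * amplitude_envelope(params, x) *
    sin(params$k * x - 2 * pi * params$f * t + params$phi)
}

midline_velocity <- function(params, x, t) {
  -2 * pi * params$f * params$L * amplitude_envelope(params, x) *
    cos(params$k * x - 2 * pi * params$f * t + params$phi)
}

#' Generate body kinematics for the prescribed carangiform motion
#'
#' Builds a closed contour (midline displaced laterally, offset by the local
#' half-width on each side) at each requested time, with the analytic
#' material velocity `v = d(dy)/dt` of every surface point and the normal
#' velocity recomputed from the contour normals.
#'
#' @param params a [carangiform_params()]
#' @param n_points number of stations along the body (per side); >= 8
#' @param times sample times
#' @return a [body_kinematics()] object; contours are ordered nose -> tail
#'   along the left (+y) side then tail -> nose along the right side, with
#'   `station` and `side` columns set
#' @export
carangiform_kinematics <- function(params, n_points = 40, times = 0) {
  stopifnot(inherits(params, "carangiform_params"))
  if (n_points < 8) stop("need at least 8 surface points per side")
  s <- seq(0, 1, length.out = n_points)
  x <- s * params$L
  w <- params$L * params$halfwidth(s)
  contours <- lapply(times, function(t) {
    ym <- midline_displacement(params, x, t)
    vm <- midline_velocity(params, x, t)
    # left side nose->tail, right side tail->nose; interior stations only on
    # the return leg so nose and tail vertices are not duplicated
    i2 <- seq(n_points - 1, 2)
    data.frame(
      x = c(x, x[i2]),
      y = c(ym + w, ym[i2] - w[i2]),
      u = 0,
      v = c(vm, vm[i2]),
      station = c(s, s[i2]),
      side = c(rep("left", n_points), rep("right", length(i2))))
  })
  body_kinematics(times, contours)
}

#' Mask grid nodes inside the body contour
#'
#' Sets the validity mask of a velocity series to `FALSE` for every grid
#' node inside (or on) the body contour at the matching time, emulating the
#' removal of PIV vectors measured within the fish silhouette. Masking is
#' idempotent and acts per time step; nodes already masked stay masked.
#'
#' @param series a [velocity_series()]
#' @param kinematics a [body_kinematics()] whose times cover the series times
#' @return the series with an updated mask
#' @export
mask_body_interior <- function(series, kinematics) {
  stopifnot(inherits(series, "velocity_series"),
            inherits(kinematics, "body_kinematics"))
  grid <- expand.grid(x = series$x, y = series$y, KEEP.OUT.ATTRS = FALSE)
  for (it in seq_along(series$t)) {
    ct <- contour_at(kinematics, series$t[it])
    inside <- point_in_polygon(grid$x, grid$y, ct$x, ct$y)
    m <- series$mask[, , it]
    m[matrix(inside, length(series$x), length(series$y))] <- FALSE
    series$mask[, , it] <- m
  }
  series
}
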