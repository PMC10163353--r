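#' Unsteady potential-flow swimmer surrogate with exact pressure
#'
#' Analytic ground-truth flow standing in for a mid-plane velocity slice
#' around an undulating carangiform swimmer. The flow is a uniform free
#' stream plus potential dipoles placed along the body midline; the dipoles
#' translate laterally with the prescribed midline motion, so the flow is
#' genuinely unsteady. Because the field is harmonic, the viscous term
#' vanishes identically and the unsteady Bernoulli relation gives the exact
#' pressure `p = (U_inf^2 - |u|^2) / 2 - d(phi)/dt` (referenced to zero far
#' from the body) for the incompressible Navier-Stokes equations at any
#' Reynolds number.
#'
#' The dipole singularities lie on the midline, strictly inside the body
#' contour (midline +/- half-width); grid nodes inside the contour are
#' masked, so all valid nodes see a regular field. An error is raised if any
#' singularity falls in the unmasked region.
#'
#' @param params a [carangiform_params()]
#' @param nx,ny grid size; the default grid spans `x` in `[-0.2, 1.3]`, `y`
#'   in `[-0.3, 0.3]` at spacing 0.02 body lengths
#' @param times sample times in tail-beat periods
#' @param U_inf free-stream (swimming) speed, nondimensional
#' @param n_dipoles number of dipoles along the midline; strengths scale
#'   with the local half-width squared so the nose region carries a
#'   stagnation-like positive head pressure and the surface pressure varies
#'   on scales comparable to the body half-width
#' @param n_surface_points contour stations per side for the kinematics
#' @param xlim,ylim grid extents
#' @return list with `velocity`, `pressure` (gauge `zero_at_boundary`,
#'   referenced to the far field) and `kinematics`
#' @export
potential_swimmer_truth <- function(params = carangiform_params(),
                                    nx = 76, ny = 31,
                                    times = seq(0, 0.2, by = 0.02),
                                    U_inf = 1, n_dipoles = 3,
                                    n_surface_points = 60,
                                    xlim = c(-0.2, 1.3), ylim = c(-0.3, 0.3)) {
  stopifnot(inherits(params, "carangiform_params"))
  x <- seq(xlim[1], xlim[2], length.out = nx)
  y <- seq(ylim[1], ylim[2], length.out = ny)
  kin <- carangiform_kinematics(params, n_points = n_surface_points,
                                times = times)
  dp <- swimmer_dipoles(params, U_inf, n_dipoles)
  sx <- dp$sx; mu <- dp$mu
  dims <- c(nx, ny, length(times))
  u <- array(0, dims); v <- array(0, dims); p <- array(0, dims)
  gz <- outer(x, rep(1, ny)) + 1i * outer(rep(1, nx), y)
  for (it in seq_along(times)) {
    t <- times[it]
    zs <- sx + 1i * midline_displacement(params, sx, t)
    zdot <- 1i * midline_velocity(params, sx, t)
    wvel <- matrix(U_inf + 0i, nx, ny)  # conjugate velocity u - i v
    phit <- matrix(0, nx, ny)           # d(phi)/dt
    for (i in seq_along(sx)) {
      dz <- gz - zs[i]
      wvel <- wvel - mu[i] / dz^2
      phit <- phit + Re(mu[i] * zdot[i] / dz^2)
    }
    u[, , it] <- Re(wvel)
    v[, , it] <- -Im(wvel)
    p[, , it] <- (U_inf^2 - abs(wvel)^2) / 2 - phit
  }
  # grid nodes coinciding with a singularity produce non-finite values; they
  # are only admissible if the mask covers them
  bad <- !is.finite(u) | !is.finite(v) | !is.finite(p)
  u[bad] <- 0; v[bad] <- 0; p[bad] <- 0
  vel <- velocity_series(x, y, times, u, v)
  vel <- mask_body_interior(vel, kin)
  if (any(bad & vel$mask))
    stop("singularity inside unmasked region: dipole field evaluated at an unmasked node")
  # singularities must be masked: each must fall inside the contour
  for (it in seq_along(times)) {
    ct <- kin$contours[[it]]
    zi <- sx + 1i * midline_displacement(params, sx, times[it])
    if (!all(point_in_polygon(Re(zi), Im(zi), ct$x, ct$y)))
      stop("singularity inside unmasked region: dipole outside the body contour")
  }
  pres <- pressure_series(x, y, times, p, gauge = "zero_at_boundary",
                          mask = vel$mask)
  list(velocity = vel, pressure = pres, kinematics = kin)
}

# Exact surrogate surface pressure sampled on the contour points of `kin`
# at every time (evaluating the same Bernoulli relation on the contour).
swimmer_surface_pressure <- function(params, kin, U_inf = 1, n_dipoles = 3) {
  dp <- swimmer_dipoles(params, U_inf, n_dipoles)
  sx <- dp$sx; mu <- dp$mu
  lapply(seq_along(kin$times), function(it) {
    t <- kin$times[it]
    ct <- kin$contours[[it]]
    z <- ct$x + 1i * ct$y
    zs <- sx + 1i * midline_displacement(params, sx, t)
    zdot <- 1i * midline_velocity(params, sx, t)
    wvel <- U_inf + 0i
    phit <- 0
    for (i in seq_along(sx)) {
      dz <- z - zs[i]
      wvel <- wvel - mu[i] / dz^2
      phit <- phit + Re(mu[i] * zdot[i] / dz^2)
    }
    data.frame(station = ct$station, side = ct$side, x = ct$x, y = ct$y,
               p = (U_inf^2 - abs(wvel)^2) / 2 - phit)
  })
}

# dipole layout shared by the field and surface evaluations: stations in the
# thick mid-body, strength U * halfwidth^2; keeping the singularities deep
# (contour-to-dipole distance ~ the maximum half-width) keeps the
# near-surface pressure variation on scales a coordinate network and a
# PIV-resolution grid can both resolve
swimmer_dipoles <- function(params, U_inf, n_dipoles) {
  sx <- seq(0.35, 0.65, length.out = n_dipoles) * params$L
  mu <- U_inf * (params$L * params$halfwidth(sx / params$L))^2
  list(sx = sx, mu = mu)
}
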