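#' Options for the pressure-Poisson baseline
#'
#' @param boundary treatment of the external edges:
#'   `"neumann_from_momentum"` imposes the momentum-derived normal pressure
#'   gradient (the consistent choice; the solution is then determined up to
#'   a constant and returned in the `zero_mean` gauge) or `"dirichlet_zero"`
#'   (the solution is pinned to zero on the edges)
#' @param viscous include the viscous term in the momentum-derived source
#' @param time_scheme finite-difference scheme for the unsteady term:
#'   central differences with second-order one-sided stencils at the series
#'   endpoints
#' @return an object of class `"poisson_options"`
#' @export
poisson_options <- function(boundary = c("neumann_from_momentum",
                                         "dirichlet_zero"),
                            viscous = TRUE,
                            time_scheme = c("central", "one_sided_ends")) {
  structure(list(boundary = match.arg(boundary), viscous = isTRUE(viscous),
                 time_scheme = match.arg(time_scheme)),
            class = "poisson_options")
}

#' Options for the multi-directional integration baseline
#'
#' @param n_ray_directions number of straight-ray directions (2, 4 or 8:
#'   the axis directions followed by the diagonals)
#' @param aggregator combine ray estimates by `"median"` (robust, the
#'   omnidirectional-integration convention) or `"mean"`
#' @param stop_at_body terminate rays at the body contour (masked region) so
#'   that unreliable near-body vectors never contaminate the estimate
#' @param boundary_values pressure anchor where rays enter the domain:
#'   a scalar (default 0, the documented zero-pressure-at-all-external-
#'   boundaries convention) or a function `f(x, y, t)` supplying known
#'   boundary pressures (used e.g. in discretization-order studies)
#' @return an object of class `"integration_options"`
#' @export
integration_options <- function(n_ray_directions = 8,
                                aggregator = c("median", "mean"),
                                stop_at_body = TRUE, boundary_values = 0) {
  if (!n_ray_directions %in% c(2, 4, 8))
    stop("n_ray_directions must be 2, 4 or 8")
  structure(list(n_ray_directions = as.integer(n_ray_directions),
                 aggregator = match.arg(aggregator),
                 stop_at_body = isTRUE(stop_at_body),
                 boundary_values = boundary_values),
            class = "integration_options")
}

# slice a 3D array along one dimension
aslice <- function(a, dim, i) {
  switch(dim, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
         a[, , i, drop = FALSE])
}
aassign <- function(a, dim, i, val) {
  switch(dim,
         { a[i, , ] <- val; a },
         { a[, i, ] <- val; a },
         { a[, , i] <- val; a })
}

# second-order first derivative along one dimension of a 3D array,
# one-sided at the ends; NA-safe (propagates NA)
array_deriv <- function(a, h, dim) {
  n <- base::dim(a)[dim]
  if (n < 3) stop("need at least 3 samples for second-order differences")
  out <- array(NA_real_, base::dim(a))
  mid <- 2:(n - 1)
  out <- aassign(out, dim, mid,
                 (aslice(a, dim, mid + 1) - aslice(a, dim, mid - 1)) / (2 * h))
  out <- aassign(out, dim, 1,
                 (-3 * aslice(a, dim, 1) + 4 * aslice(a, dim, 2) -
                    aslice(a, dim, 3)) / (2 * h))
  out <- aassign(out, dim, n,
                 (3 * aslice(a, dim, n) - 4 * aslice(a, dim, n - 1) +
                    aslice(a, dim, n - 2)) / (2 * h))
  out
}

# second derivative (central; second-order one-sided at the ends)
array_deriv2 <- function(a, h, dim) {
  n <- base::dim(a)[dim]
  if (n < 4) stop("need at least 4 samples for one-sided second derivatives")
  out <- array(NA_real_, base::dim(a))
  mid <- 2:(n - 1)
  out <- aassign(out, dim, mid,
                 (aslice(a, dim, mid + 1) - 2 * aslice(a, dim, mid) +
                    aslice(a, dim, mid - 1)) / h^2)
  out <- aassign(out, dim, 1,
                 (2 * aslice(a, dim, 1) - 5 * aslice(a, dim, 2) +
                    4 * aslice(a, dim, 3) - aslice(a, dim, 4)) / h^2)
  out <- aassign(out, dim, n,
                 (2 * aslice(a, dim, n) - 5 * aslice(a, dim, n - 1) +
                    4 * aslice(a, dim, n - 2) - aslice(a, dim, n - 3)) / h^2)
  out
}

#' Momentum-derived pressure-gradient field
#'
#' Computes the gridded pressure gradient from the non-dimensional momentum
#' balance, `grad p = -(Du/Dt) + (1/Re) laplacian(u)` per component, with
#' second-order central differences in space and time (one-sided at the
#' domain edges and series endpoints). The gradient is undefined (NA,
#' flagged in `valid`) at nodes whose finite-difference stencil touches a
#' masked node.
#'
#' @param series a [velocity_series()] with at least 3 time steps
#' @param Re Reynolds number
#' @param viscous include the viscous term
#' @return list of class `"gradient_field"` with `x`, `y`, `t`, arrays
#'   `gx`, `gy`, logical `valid`, and the node mask of the input
#' @export
pressure_gradient_field <- function(series, Re, viscous = TRUE) {
  stopifnot(inherits(series, "velocity_series"))
  if (length(series$t) < 3)
    stop("need at least 3 time steps for second-order time differences")
  h <- grid_step(series)
  u <- series$u; v <- series$v
  u[!series$mask] <- NA; v[!series$mask] <- NA
  ux <- array_deriv(u, h["dx"], 1); uy <- array_deriv(u, h["dy"], 2)
  vx <- array_deriv(v, h["dx"], 1); vy <- array_deriv(v, h["dy"], 2)
  ut <- array_deriv(u, h["dt"], 3); vt <- array_deriv(v, h["dt"], 3)
  gx <- -(ut + u * ux + v * uy)
  gy <- -(vt + u * vx + v * vy)
  if (viscous) {
    if (length(series$x) >= 4 && length(series$y) >= 4) {
      gx <- gx + (array_deriv2(u, h["dx"], 1) + array_deriv2(u, h["dy"], 2)) / Re
      gy <- gy + (array_deriv2(v, h["dx"], 1) + array_deriv2(v, h["dy"], 2)) / Re
    } else stop("grid too small for the viscous term")
  }
  valid <- is.finite(gx) & is.finite(gy)
  structure(list(x = series$x, y = series$y, t = series$t,
                 gx = gx, gy = gy, valid = valid, mask = series$mask),
            class = "gradient_field")
}

ray_directions <- function(n) {
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(-1, -1), c(-1, 1), c(1, -1))
  dirs[seq_len(n)]
}

#' Multi-directional integration of the pressure gradient
#'
#' Queen-2.0-style omnidirectional scheme: for every node and every ray
#' direction, the pressure gradient is line-integrated (trapezoid rule)
#' along the straight ray from the boundary where it enters the domain up to
#' the node, starting from the boundary anchor value; the per-ray estimates
#' are aggregated by the median. Rays are terminated when they meet the body
#' (masked region) or a node with undefined gradient, so nodes shadowed by
#' the body in some direction simply lose those rays. The result carries the
#' `zero_at_boundary` gauge.
#'
#' @param grad a [pressure_gradient_field()]
#' @param options an [integration_options()]
#' @param keep_rays also return the per-ray estimates (attribute
#'   `"ray_estimates"`, an `nx x ny x n_rays x nt` array) for diagnostics
#' @return a [pressure_series()]; nodes with undefined gradient are masked
#' @export
integrate_multidirectional <- function(grad, options = integration_options(),
                                       keep_rays = FALSE) {
  stopifnot(inherits(grad, "gradient_field"),
            inherits(options, "integration_options"))
  nx <- length(grad$x); ny <- length(grad$y); nt <- length(grad$t)
  hx <- grad$x[2] - grad$x[1]; hy <- grad$y[2] - grad$y[1]
  dirs <- ray_directions(options$n_ray_directions)
  if (any(vapply(dirs, function(d) all(d != 0), TRUE)) &&
      abs(hx - hy) > 1e-9 * max(hx, hy))
    stop("diagonal rays require equal grid spacing in x and y")
  bv <- options$boundary_values
  bfun <- if (is.function(bv)) bv else function(x, y, t) rep(bv, length(x))
  p_out <- array(NA_real_, c(nx, ny, nt))
  rays <- if (keep_rays) array(NA_real_, c(nx, ny, length(dirs), nt))
  for (it in seq_len(nt)) {
    gx <- grad$gx[, , it]; gy <- grad$gy[, , it]
    ok <- grad$valid[, , it]
    if (options$stop_at_body) ok <- ok & grad$mask[, , it]
    gx[!ok] <- NA; gy[!ok] <- NA
    est <- array(NA_real_, c(nx, ny, length(dirs)))
    for (id in seq_along(dirs)) {
      d <- dirs[[id]]
      est[, , id] <- ray_integral(gx, gy, grad$x, grad$y, grad$t[it],
                                  hx, hy, d, bfun)
    }
    if (keep_rays) rays[, , , it] <- est
    p_out[, , it] <- apply(est, c(1, 2), function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NA_real_)
      if (options$aggregator == "median") median(v) else mean(v)
    })
    if (any(ok & !is.finite(p_out[, , it])))
      stop("node enclosed by mask: no valid integration ray reaches it")
  }
  mk <- is.finite(p_out)
  p_out[!mk] <- NA
  out <- pressure_series(grad$x, grad$y, grad$t, p_out,
                         gauge = "zero_at_boundary", mask = mk)
  if (keep_rays) attr(out, "ray_estimates") <- rays
  out
}

# integrate the projected gradient along all parallel rays of direction d
# across the grid; NA gradient breaks the ray (no later anchor).
ray_integral <- function(gx, gy, xs, ys, t, hx, hy, d, bfun) {
  nx <- nrow(gx); ny <- ncol(gx)
  p <- matrix(NA_real_, nx, ny)
  # walk order along the direction
  ix <- if (d[1] > 0) 1:nx else if (d[1] < 0) nx:1 else NULL
  iy <- if (d[2] > 0) 1:ny else if (d[2] < 0) ny:1 else NULL
  step <- function(g1, g2, h) (g1 + g2) * h / 2
  if (is.null(iy)) {             # horizontal ray, one per y-row
    for (j in 1:ny) {
      prev <- NA_real_
      for (k in seq_along(ix)) {
        i <- ix[k]
        if (k == 1) {
          prev <- if (is.finite(gx[i, j])) bfun(xs[i], ys[j], t) else NA_real_
        } else {
          ip <- ix[k - 1]
          prev <- if (is.finite(prev) && is.finite(gx[i, j]) &&
                      is.finite(gx[ip, j]))
            prev + step(gx[ip, j], gx[i, j], hx) * sign(d[1]) else NA_real_
        }
        p[i, j] <- prev
      }
    }
  } else if (is.null(ix)) {      # vertical ray
    for (i in 1:nx) {
      prev <- NA_real_
      for (k in seq_along(iy)) {
        j <- iy[k]
        if (k == 1) {
          prev <- if (is.finite(gy[i, j])) bfun(xs[i], ys[j], t) else NA_real_
        } else {
          jp <- iy[k - 1]
          prev <- if (is.finite(prev) && is.finite(gy[i, j]) &&
                      is.finite(gy[i, jp]))
            prev + step(gy[i, jp], gy[i, j], hy) * sign(d[2]) else NA_real_
        }
        p[i, j] <- prev
      }
    }
  } else {                       # diagonal rays
    # enumerate all diagonal lines: constant (i - j) or (i + j)
    starts <- list()
    si <- if (d[1] > 0) 1 else nx
    sj <- if (d[2] > 0) 1 else ny
    for (i in 1:nx) starts[[length(starts) + 1]] <- c(i, sj)
    for (j in 1:ny) if (j != sj) starts[[length(starts) + 1]] <- c(si, j)
    for (s in starts) {
      i <- s[1]; j <- s[2]
      prev <- NA_real_
      first <- TRUE
      while (i >= 1 && i <= nx && j >= 1 && j <= ny) {
        if (first) {
          prev <- if (is.finite(gx[i, j]) && is.finite(gy[i, j]))
            bfun(xs[i], ys[j], t) else NA_real_
          first <- FALSE
        } else {
          ip <- i - d[1]; jp <- j - d[2]
          good <- is.finite(prev) && is.finite(gx[i, j]) &&
            is.finite(gy[i, j]) && is.finite(gx[ip, jp]) &&
            is.finite(gy[ip, jp])
          prev <- if (good)
            prev + step(gx[ip, jp], gx[i, j], hx) * sign(d[1]) +
                   step(gy[ip, jp], gy[i, j], hy) * sign(d[2])
          else NA_real_
        }
        p[i, j] <- prev
        i <- i + d[1]; j <- j + d[2]
      }
    }
  }
  p
}

#' Pressure-Poisson baseline
#'
#' Solves the five-point discrete Poisson equation
#' `laplacian(p) = div(g)` where `g` is the momentum-derived pressure
#' gradient of [pressure_gradient_field()] (the divergence of the material
#' derivative, plus the optional viscous source), one time step at a time.
#' Masked (body-interior) nodes and nodes with undefined gradient are
#' excluded from the system; at interfaces to excluded nodes and -- under
#' the `neumann_from_momentum` option -- at the external edges, the
#' momentum-derived normal gradient closes the stencil via a reflected
#' ghost node. The all-Neumann system is solved with a zero-mean constraint
#' (Lagrange multiplier), giving the `zero_mean` gauge; `dirichlet_zero`
#' pins the edges and gives `zero_at_boundary`.
#'
#' @param series a [velocity_series()]
#' @param Re Reynolds number
#' @param options a [poisson_options()]
#' @return a [pressure_series()]
#' @export
solve_poisson <- function(series, Re, options = poisson_options()) {
  stopifnot(inherits(series, "velocity_series"),
            inherits(options, "poisson_options"))
  grad <- pressure_gradient_field(series, Re, viscous = options$viscous)
  nx <- length(grad$x); ny <- length(grad$y); nt <- length(grad$t)
  hx <- grad$x[2] - grad$x[1]; hy <- grad$y[2] - grad$y[1]
  if (abs(hx - hy) > 1e-9 * max(hx, hy))
    stop("Poisson solver requires equal grid spacing in x and y")
  h <- hx
  p_out <- array(NA_real_, c(nx, ny, nt))
  dirich <- options$boundary == "dirichlet_zero"
  for (it in seq_len(nt)) {
    gx <- grad$gx[, , it]; gy <- grad$gy[, , it]
    ok <- grad$valid[, , it] & series$mask[, , it]
    # source: divergence of the gradient field (second-order, one-sided at
    # domain edges)
    src <- array_deriv(array(gx, c(nx, ny, 1)), h, 1)[, , 1] +
           array_deriv(array(gy, c(nx, ny, 1)), h, 2)[, , 1]
    solve_nodes <- ok & is.finite(src)
    idx <- matrix(0L, nx, ny)
    ids <- which(solve_nodes)
    idx[ids] <- seq_along(ids)
    n <- length(ids)
    if (n == 0) next
    ij <- arrayInd(ids, c(nx, ny))
    iq <- ij[, 1]; jq <- ij[, 2]
    edge_node <- iq == 1 | iq == nx | jq == 1 | jq == ny
    pinned <- dirich & edge_node
    rhs <- ifelse(pinned, 0, src[ids])
    diag_c <- numeric(n)
    ti <- list(); tj <- list(); tx <- list()
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- iq + dd[1]; jj <- jq + dd[2]
      inb <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
      nid <- integer(n)
      nid[inb] <- idx[cbind(ii[inb], jj[inb])]
      gn <- if (dd[1] != 0) gx[ids] * dd[1] else gy[ids] * dd[2]
      # interior pair: standard five-point coupling
      A <- !pinned & inb & nid > 0
      # external-edge ghost reflected through the node with the
      # momentum-derived normal gradient: p_ghost = p_opp + 2 h g.n
      oi <- iq - dd[1]; oj <- jq - dd[2]
      oinb <- oi >= 1 & oi <= nx & oj >= 1 & oj <= ny
      onid <- integer(n)
      onid[oinb] <- idx[cbind(oi[oinb], oj[oinb])]
      B <- !pinned & !inb & onid > 0
      # immersed-interface one-sided closure p_ghost = p_node + h g.n:
      # the pair term reduces to a pure source contribution
      C <- !pinned & !A & !B
      ti <- c(ti, list(which(A), which(B)))
      tj <- c(tj, list(nid[A], onid[B]))
      tx <- c(tx, list(rep(1 / h^2, sum(A)), rep(1 / h^2, sum(B))))
      diag_c[A | B] <- diag_c[A | B] - 1 / h^2
      rhs[B] <- rhs[B] - 2 * gn[B] / h
      rhs[C] <- rhs[C] - gn[C] / h
    }
    qn <- seq_len(n)
    trip_i <- c(unlist(ti), qn)
    trip_j <- c(unlist(tj), qn)
    trip_x <- c(unlist(tx), ifelse(pinned, 1, diag_c))
    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(n, n))
    if (dirich) {
      sol <- as.numeric(Matrix::solve(A, rhs))
    } else {
      # zero-mean constraint via Lagrange multiplier
      Aaug <- rbind(cbind(A, Matrix::Matrix(1, n, 1)),
                    cbind(Matrix::Matrix(1, 1, n), Matrix::Matrix(0, 1, 1)))
      sol <- as.numeric(Matrix::solve(Aaug, c(rhs, 0)))[seq_len(n)]
    }
    pm <- matrix(NA_real_, nx, ny)
    pm[ids] <- sol
    p_out[, , it] <- pm
  }
  mk <- is.finite(p_out)
  pressure_series(grad$x, grad$y, grad$t, p_out,
                  gauge = if (dirich) "zero_at_boundary" else "zero_mean",
                  mask = mk)
}

#' Nearest-grid-node surface pressure (baseline extrapolation)
#'
#' The grid-based baselines cannot evaluate pressure on the body surface;
#' the conventional workaround copies the pressure of the nearest valid
#' (unmasked, finite) grid node to each contour point. The Euclidean
#' extrapolation distance is reported per point; it grows with the grid
#' spacing. Equidistant ties resolve to the lowest node index in
#' column-major (x-fastest) order.
#'
#' @param pressure a [pressure_series()]
#' @param kinematics a [body_kinematics()]
#' @param times evaluation times (default: all pressure-series times)
#' @return data frame with `time`, `station`, `side`, `x`, `y`, `p`,
#'   `extrap_dist`
#' @export
nearest_point_surface_pressure <- function(pressure, kinematics,
                                           times = NULL) {
  stopifnot(inherits(pressure, "pressure_series"),
            inherits(kinematics, "body_kinematics"))
  times <- times %||% pressure$t
  grid <- as.matrix(expand.grid(x = pressure$x, y = pressure$y,
                                KEEP.OUT.ATTRS = FALSE))
  out <- do.call(rbind, lapply(times, function(tt) {
    itime <- which.min(abs(pressure$t - tt))
    if (abs(pressure$t[itime] - tt) > 1e-8)
      stop(sprintf("no pressure sample at requested time %g", tt))
    pm <- pressure$p[, , itime]
    okn <- which(as.vector(pressure$mask[, , itime]) & is.finite(as.vector(pm)))
    if (length(okn) == 0) stop("no valid pressure node at this time")
    ct <- contour_at(kinematics, tt)
    gx <- grid[okn, 1]; gy <- grid[okn, 2]; pv <- as.vector(pm)[okn]
    res <- vapply(seq_len(nrow(ct)), function(ipt) {
      d2 <- (gx - ct$x[ipt])^2 + (gy - ct$y[ipt])^2
      k <- which.min(d2)  # first minimum = lowest node index
      c(pv[k], sqrt(d2[k]))
    }, numeric(2))
    df <- data.frame(time = tt,
                     station = if (!is.null(ct$station)) ct$station else NA,
                     side = if (!is.null(ct$side)) ct$side else NA,
                     x = ct$x, y = ct$y, p = res[1, ], extrap_dist = res[2, ])
    df[order(df$side, df$station), ]
  }))
  rownames(out) <- NULL
  out
}
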