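test_that("pressure gradient: uniform flow, rigid rotation, analytic orders", {
  # uniform steady flow -> zero gradient
  dims <- c(8, 8, 4)
  uni <- velocity_series(0:7 / 7, 0:7 / 7, 0:3 / 3,
                         array(0.4, dims), array(-0.2, dims))
  g <- pressure_gradient_field(uni, Re = 100, viscous = TRUE)
  expect_equal(max(abs(g$gx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(g$gy)), 0, tolerance = 1e-12)
  # rigid rotation (u, v) = (-y, x), inviscid steady: grad p = (x, y)
  n <- 21
  xs <- seq(-1, 1, length.out = n)
  u <- array(rep(-xs, each = n), c(n, n, 3))
  v <- array(rep(xs, times = n), c(n, n, 3))
  rot <- velocity_series(xs, xs, 0:2, u, v)
  gr <- pressure_gradient_field(rot, Re = 1e12, viscous = FALSE)
  gx_true <- outer(xs, rep(1, n))
  gy_true <- outer(rep(1, n), xs)
  expect_equal(gr$gx[, , 2], gx_true, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(gr$gy[, , 2], gy_true, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pressure_gradient_field(
    velocity_series(0:4 / 4, 0:4 / 4, 0:1,
                    array(0, c(5, 5, 2)), array(0, c(5, 5, 2))), 10),
    "3 time steps")
})

test_that("gradient is flagged undefined next to masked nodes", {
  tg <- tiny_tg(12, 4)
  s <- tg$velocity
  s$mask[6, 6, 2] <- FALSE
  g <- pressure_gradient_field(s, 100)
  expect_false(g$valid[6, 6, 2])
  expect_false(g$valid[5, 6, 2])   # spatial neighbor
  expect_false(g$valid[6, 6, 3])   # temporal neighbor
  expect_true(g$valid[3, 3, 2])
})

test_that("multi-directional integration: zero and constant gradients", {
  dims <- c(9, 9, 3)
  still <- velocity_series(0:8 / 8, 0:8 / 8, 0:2,
                           array(0, dims), array(0, dims))
  g0 <- pressure_gradient_field(still, 10)
  p0 <- integrate_multidirectional(g0)
  expect_equal(max(abs(p0$p)), 0, tolerance = 1e-12)
  # constant gradient (1, 0): with boundary anchors from the closed form
  # p = x, all rays agree exactly (path independence) and recover it
  g1 <- g0
  g1$gx[] <- 1
  opts <- integration_options(boundary_values = function(x, y, t) x)
  p1 <- integrate_multidirectional(g1, opts, keep_rays = TRUE)
  rays <- attr(p1, "ray_estimates")
  spread <- apply(rays, c(1, 2, 4), function(v)
    diff(range(v[is.finite(v)])))
  expect_lt(max(spread), 1e-10)
  expect_equal(p1$p[, , 1], outer(g1$x, rep(1, 9)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # median aggregation is invariant under ray reordering
  perm <- c(3, 1, 4, 2, 8, 6, 7, 5)
  agg <- apply(rays[, , perm, , drop = FALSE], c(1, 2, 4), function(v)
    median(v[is.finite(v)]))
  expect_equal(agg[, , 1], p1$p[, , 1], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rays terminate at the body and fully enclosed nodes error", {
  dims <- c(11, 11, 3)
  still <- velocity_series(0:10 / 10, 0:10 / 10, 0:2,
                           array(0, dims), array(0, dims))
  g <- pressure_gradient_field(still, 10)
  # an annular mask: the center node keeps no unbroken ray to any boundary
  g$valid[4:8, 4:8, ] <- FALSE
  g$valid[6, 6, ] <- TRUE
  expect_error(integrate_multidirectional(g), "enclosed")
})

test_that("integration converges at second order on the Taylor-Green field", {
  Re <- 100
  err <- function(n) {
    tg <- taylor_green_truth(n, n, times = seq(0, 0.04, by = 0.01), Re = Re)
    g <- pressure_gradient_field(tg$velocity, Re)
    bf <- function(x, y, t) pivpressure:::taylor_green_fields(x, y, t, Re)$p
    p <- integrate_multidirectional(g, integration_options(boundary_values = bf))
    field_rmse(p, tg$pressure)
  }
  e1 <- err(17); e2 <- err(33)
  expect_gt(e1 / e2, 3); expect_lt(e1 / e2, 5.5)
})

test_that("Poisson solve: trivial case, manufactured solution, conservation", {
  dims <- c(9, 9, 3)
  still <- velocity_series(0:8 / 8, 0:8 / 8, 0:2,
                           array(0, dims), array(0, dims))
  p0 <- solve_poisson(still, 10, poisson_options("dirichlet_zero"))
  expect_equal(max(abs(p0$p)), 0, tolerance = 1e-10)
  # manufactured solution p = sin(x) sin(y) via a rigid-rotation-free field:
  # use Taylor-Green at two resolutions and check the order
  Re <- 100
  err <- function(n, boundary) {
    tg <- taylor_green_truth(n, n, times = seq(0, 0.04, by = 0.01), Re = Re)
    field_rmse(solve_poisson(tg$velocity, Re, poisson_options(boundary)),
               tg$pressure)
  }
  e1 <- err(33, "neumann_from_momentum"); e2 <- err(65, "neumann_from_momentum")
  expect_gt(e1 / e2, 3.2); expect_lt(e1 / e2, 5.5)
  # discrete conservation: the five-point residual of the solution matches
  # the divergence source at interior nodes to solver precision
  tg <- tiny_tg(16, 4)
  sol <- solve_poisson(tg$velocity, 100)
  g <- pressure_gradient_field(tg$velocity, 100)
  h <- tg$velocity$x[2] - tg$velocity$x[1]
  p <- sol$p[, , 2]
  i <- 2:15
  lap <- (p[i + 1, i] + p[i - 1, i] + p[i, i + 1] + p[i, i - 1] -
            4 * p[i, i]) / h^2
  src <- (g$gx[i + 1, i, 2] - g$gx[i - 1, i, 2] +
            g$gy[i, i + 1, 2] - g$gy[i, i - 1, 2]) / (2 * h)
  # the zero-mean constraint distributes the compatibility defect as a
  # single Lagrange-multiplier constant over all rows
  resid <- lap - src
  expect_lt(max(abs(resid - mean(resid))), 1e-8)
})

test_that("nearest-node surface extrapolation: values, ties and distances", {
  dims <- c(5, 5, 3)
  p <- array(seq_len(prod(dims)), dims)
  ps <- pressure_series(0:4 / 4, 0:4 / 4, 0:2, p, gauge = "zero_mean")
  kin <- body_kinematics(0:2, lapply(0:2, function(t)
    data.frame(x = c(0.5, 0.75, 0.5, 0.25), y = c(0.375, 0.5, 0.6, 0.5),
               u = 0, v = 0)))
  sp <- nearest_point_surface_pressure(ps, kin, times = 0)
  # contour point (0.75, 0.5) coincides with node (4, 3): exact value, zero
  # distance
  hit <- sp[abs(sp$x - 0.75) < 1e-12, ]
  expect_equal(hit$extrap_dist, 0)
  expect_equal(hit$p, p[4, 3, 1])
  # equidistant tie resolves to the lowest column-major node index
  tie <- sp[abs(sp$x - 0.5) < 1e-12 & abs(sp$y - 0.375) < 1e-12, ]
  # (0.5, 0.375) is equidistant between nodes (3,2) and (3,3): keep (3,2),
  # the lower column-major index
  expect_equal(tie$p, p[3, 2, 1])
  # extrapolation distance grows under coarsening
  params <- carangiform_params()
  sw <- potential_swimmer_truth(params, times = seq(0, 0.04, by = 0.02))
  pres_f <- sw$pressure
  pres_c <- pressure_series(pres_f$x[seq(1, 76, 5)], pres_f$y[seq(1, 31, 5)],
                            pres_f$t,
                            pres_f$p[seq(1, 76, 5), seq(1, 31, 5), ],
                            gauge = pres_f$gauge,
                            mask = pres_f$mask[seq(1, 76, 5), seq(1, 31, 5), ])
  df <- nearest_point_surface_pressure(pres_f, sw$kinematics, 0)
  dc <- nearest_point_surface_pressure(pres_c, sw$kinematics, 0)
  expect_gt(mean(dc$extrap_dist), 2 * mean(df$extrap_dist))
})
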