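test_that("carangiform amplitude envelope matches its prescription", {
  p <- carangiform_params()
  expect_equal(amplitude_envelope(p, 0), 0.02)
  expect_equal(amplitude_envelope(p, p$L), 0.02 - 0.08 + 0.16)  # 0.10 at tail
  # at phase kx - 2 pi f t + phi = 0 the displacement vanishes and the
  # lateral velocity is -2 pi f A(x)
  x <- 0.3; t <- (p$k * x + p$phi) / (2 * pi * p$f)
  expect_equal(pivpressure:::midline_displacement(p, x, t), 0)
  expect_equal(pivpressure:::midline_velocity(p, x, t),
               -2 * pi * p$f * amplitude_envelope(p, x))
  # displacement bounded by the envelope maximum
  kin <- carangiform_kinematics(p, 50, times = seq(0, 1, by = 0.1))
  for (ct in kin$contours) {
    dy <- abs(ct$y) - p$halfwidth(ct$station)
    expect_lte(max(dy), max(amplitude_envelope(p, seq(0, 1, 0.01))) + 1e-9)
  }
})

test_that("kinematics invariants: closed contour, unit outward normals, u_n", {
  kin <- carangiform_kinematics(carangiform_params(), 30,
                                times = c(0, 0.25, 0.5))
  for (ct in kin$contours) {
    expect_equal(sqrt(ct$nx^2 + ct$ny^2), rep(1, nrow(ct)), tolerance = 1e-9)
    expect_equal(ct$un, ct$u * ct$nx + ct$v * ct$ny, tolerance = 1e-12)
    eps <- 1e-7
    expect_false(any(point_in_polygon(ct$x + eps * ct$nx, ct$y + eps * ct$ny,
                                      ct$x, ct$y)))
  }
})

test_that("surface normal velocity matches a finite-difference motion oracle", {
  p <- carangiform_params()
  dt <- 1e-5
  t0 <- 0.13
  kin <- carangiform_kinematics(p, 40, times = c(t0 - dt, t0, t0 + dt))
  ct <- kin$contours[[2]]
  # displacement of each material surface point between t0 - dt and t0 + dt
  vy_fd <- (kin$contours[[3]]$y - kin$contours[[1]]$y) / (2 * dt)
  un_fd <- 0 * ct$nx + vy_fd * ct$ny
  expect_equal(ct$un, un_fd, tolerance = 1e-6)
})

test_that("kinematics are periodic with the tail-beat period", {
  p <- carangiform_params(f = 2)  # period 0.5
  k1 <- carangiform_kinematics(p, 20, times = 0.1)
  k2 <- carangiform_kinematics(p, 20, times = 0.1 + 1 / p$f)
  expect_equal(k1$contours[[1]]$y, k2$contours[[1]]$y, tolerance = 1e-12)
  expect_equal(k1$contours[[1]]$v, k2$contours[[1]]$v, tolerance = 1e-12)
})

test_that("body-interior masking matches a brute-force point-in-polygon count", {
  skip_if_not_installed("mgcv")
  p <- carangiform_params()
  kin <- carangiform_kinematics(p, 40, times = c(0, 0.3))
  dims <- c(40, 21, 2)
  # grid offset by irrational-ish amounts so no node falls exactly on the
  # contour (the oracle's on-boundary behavior is unspecified)
  ser <- velocity_series(seq(-0.1037, 1.1963, length.out = 40),
                         seq(-0.2471, 0.2529, length.out = 21), c(0, 0.3),
                         array(0, dims), array(0, dims))
  masked <- mask_body_interior(ser, kin)
  grid <- expand.grid(x = ser$x, y = ser$y)
  for (it in 1:2) {
    ct <- kin$contours[[it]]
    oracle <- mgcv::in.out(cbind(c(ct$x, ct$x[1]), c(ct$y, ct$y[1])),
                           as.matrix(grid))
    expect_equal(sum(!masked$mask[, , it]), sum(oracle))
  }
  # node at the body centroid is masked, a far node is not
  ct <- kin$contours[[1]]
  expect_true(point_in_polygon(mean(ct$x), mean(ct$y), ct$x, ct$y))
  expect_false(point_in_polygon(-0.1, 0.25, ct$x, ct$y))
  # masking is idempotent
  expect_identical(mask_body_interior(masked, kin)$mask, masked$mask)
  # and time-local: time 1 mask depends only on the time-1 contour
  expect_true(any(masked$mask[, , 1] != masked$mask[, , 2]))
})

test_that("an open contour is rejected", {
  expect_error(body_kinematics(0, list(data.frame(
    x = c(0, 1, 2), y = c(0, 0, 0), u = 0, v = 0))), "open|degenerate")
})
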