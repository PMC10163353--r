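test_that("Taylor-Green truth decays viscously and has a zero-mean gauge", {
  Re <- 100
  t1 <- Re / 2  # viscous decay factor exp(-2 t / Re) = exp(-1)
  tg <- taylor_green_truth(24, 24, times = c(0, t1), Re = Re)
  ratio <- max(abs(tg$velocity$u[, , 2])) / max(abs(tg$velocity$u[, , 1]))
  expect_equal(ratio, exp(-1), tolerance = 1e-12)
  for (it in 1:2)
    expect_equal(mean(tg$pressure$p[, , it]), 0, tolerance = 1e-12)
})

test_that("Taylor-Green satisfies the momentum equations to second order", {
  Re <- 80
  res_norm <- function(n) {
    h <- 2 * pi / (n - 1); dt <- 0.01
    tg <- taylor_green_truth(n, n, times = c(0, dt, 2 * dt), Re = Re)
    u <- tg$velocity$u; v <- tg$velocity$v; p <- tg$pressure$p
    i <- 3:(n - 2)
    ux <- (u[i + 1, i, 2] - u[i - 1, i, 2]) / (2 * h)
    uy <- (u[i, i + 1, 2] - u[i, i - 1, 2]) / (2 * h)
    ut <- (u[i, i, 3] - u[i, i, 1]) / (2 * dt)
    px <- (p[i + 1, i, 2] - p[i - 1, i, 2]) / (2 * h)
    uxx <- (u[i + 1, i, 2] - 2 * u[i, i, 2] + u[i - 1, i, 2]) / h^2
    uyy <- (u[i, i + 1, 2] - 2 * u[i, i, 2] + u[i, i - 1, 2]) / h^2
    max(abs(ut + u[i, i, 2] * ux + v[i, i, 2] * uy + px - (uxx + uyy) / Re))
  }
  e1 <- res_norm(64); e2 <- res_norm(128)
  expect_lt(e2, e1)
  expect_gt(e1 / e2, 3)  # about 4 for a second-order scheme
  expect_lt(e1 / e2, 5)
})

test_that("swimmer surrogate satisfies the Euler equations to second order", {
  resid_med <- function(nx, ny, dt_frac) {
    sw <- potential_swimmer_truth(nx = nx, ny = ny,
                                  times = c(0, dt_frac, 2 * dt_frac))
    v <- sw$velocity; p <- sw$pressure$p
    h <- v$x[2] - v$x[1]; dt <- v$t[2] - v$t[1]
    i <- 2:(length(v$x) - 1); j <- 2:(length(v$y) - 1)
    u <- v$u
    ex <- (u[i, j, 3] - u[i, j, 1]) / (2 * dt) +
      u[i, j, 2] * (u[i + 1, j, 2] - u[i - 1, j, 2]) / (2 * h) +
      v$v[i, j, 2] * (u[i, j + 1, 2] - u[i, j - 1, 2]) / (2 * h) +
      (p[i + 1, j, 2] - p[i - 1, j, 2]) / (2 * h)
    # far-field band, away from the masked body and its steep gradients
    far <- abs(matrix(v$y[j], length(i), length(j), byrow = TRUE)) > 0.22
    median(abs(ex[far]))
  }
  e1 <- resid_med(76, 31, 0.02)
  e2 <- resid_med(151, 61, 0.01)
  expect_lt(e1, 2e-3)
  expect_gt(e1 / e2, 3); expect_lt(e1 / e2, 5.5)
})

test_that("swimmer surrogate masks its singularities and is well scaled", {
  params <- carangiform_params()
  sw <- potential_swimmer_truth(params, times = c(0, 0.02))
  dp <- pivpressure:::swimmer_dipoles(params, 1, 3)
  for (it in 1:2) {
    ct <- sw$kinematics$contours[[it]]
    ys <- pivpressure:::midline_displacement(params, dp$sx, sw$velocity$t[it])
    expect_true(all(point_in_polygon(dp$sx, ys, ct$x, ct$y)))
  }
  # the head pressure normalizer is positive and O(0.1 U^2)
  st <- swimmer_surface_truth(params, sw$kinematics)
  expect_gt(head_pressure(st), 0.1)
  expect_lt(max(abs(st$p)), 3)
})

test_that("zero free stream with vanishing dipole strengths gives rest", {
  params <- carangiform_params(a0 = 0, a1 = 0, a2 = 0)
  sw <- potential_swimmer_truth(params, times = c(0, 0.02), U_inf = 0)
  ok <- sw$velocity$mask
  expect_equal(max(abs(sw$velocity$u[ok])), 0)
  expect_equal(max(abs(sw$velocity$v[ok])), 0)
  expect_equal(max(sw$pressure$p[ok]) - min(sw$pressure$p[ok]), 0)
})

test_that("downsampling is pure subsampling and composes", {
  tg <- tiny_tg(16, 5)
  expect_series_equal(downsample_series(tg$velocity, 1, 1), tg$velocity)
  d3 <- downsample_series(tg$velocity, 3, 2)
  expect_equal(d3$x, tg$velocity$x[seq(1, 16, by = 3)])
  expect_equal(d3$u[2, 2, 2], tg$velocity$u[4, 4, 3])
  # composition: 2 then 3 equals 6 in space (using a 49-node axis)
  tg2 <- taylor_green_truth(49, 49, times = c(0, 0.1), Re = 50)
  expect_series_equal(
    downsample_series(downsample_series(tg2$velocity, 2), 3),
    downsample_series(tg2$velocity, 6))
  expect_error(downsample_series(tg$velocity, 1.5), "integer")
  # 50 nodes spanning about one body length at 0.02 L keep 10 at 0.1 L
  body_axis <- downsample_series(
    velocity_series(seq(0, 0.98, by = 0.02), 0:1, 0:2,
                    array(0, c(50, 2, 3)), array(0, c(50, 2, 3))), 5)
  expect_equal(length(body_axis$x), 10)
})

test_that("noise injection is seeded, masked and correctly scaled", {
  tg <- tiny_tg(16, 4)
  s <- tg$velocity
  s$mask[1:4, 1:4, 1] <- FALSE
  expect_identical(add_noise(s, 0), s)
  n1 <- add_noise(s, 0.1, seed = 7)
  n2 <- add_noise(s, 0.1, seed = 7)
  expect_identical(n1$u, n2$u)
  expect_false(identical(n1$u, add_noise(s, 0.1, seed = 8)$u))
  # masked nodes untouched
  expect_identical(n1$u[!s$mask], s$u[!s$mask])
  # empirical noise sd within 2% of target over >= 1e5 samples
  big <- velocity_series(seq(0, 1, length.out = 240),
                         seq(0, 1, length.out = 240), c(0, 1),
                         array(1, c(240, 240, 2)), array(0, c(240, 240, 2)))
  lev <- 0.05
  nb <- add_noise(big, lev, seed = 1)   # U_ref = 1
  expect_equal(sd(nb$u - big$u), lev, tolerance = 0.02)
  expect_equal(mean(nb$u - big$u), 0, tolerance = 1e-3)
})

test_that("degradation commutes with non-dimensionalization", {
  sc <- scaling_set(L = 2, T = 5, Re = 40)
  dims <- c(13, 13, 5)
  dimser <- velocity_series(seq(0, 2, length.out = 13),
                            seq(0, 2, length.out = 13),
                            seq(0, 5, length.out = 5),
                            array(rnorm(prod(dims)), dims),
                            array(rnorm(prod(dims)), dims),
                            units = "dimensional")
  a <- nondimensionalize(downsample_series(dimser, 3, 2), sc)
  b <- downsample_series(nondimensionalize(dimser, sc), 3, 2)
  expect_series_equal(a, b)
  # noise with the same seed: scale-covariant, so the operations commute
  an <- nondimensionalize(add_noise(dimser, 0.1, seed = 3), sc)
  bn <- add_noise(nondimensionalize(dimser, sc), 0.1, seed = 3)
  expect_series_equal(an, bn, tol = 1e-12)
})
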