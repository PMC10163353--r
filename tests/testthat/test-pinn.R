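# Small-scale training behavior. These use deliberately tiny networks and
# few epochs; accuracy-level checks live in the validation suite.

short_fit <- function(epochs = 8, seed = 1, tg = tiny_tg(12, 4),
                      weights = loss_weights()) {
  pinn(tg$velocity, Re = 100,
       network = network_config(2, 16, "tanh", init_seed = seed),
       training = training_config(epochs = epochs, minibatch = 4096,
                                  learning_rate = 5e-3, lr_decay = 1,
                                  lr_decay_every = 1000,
                                  sampling_seed = seed + 100L),
       weights = weights)
}

test_that("training is reproducible from its two seeds", {
  f1 <- short_fit(epochs = 5)
  f2 <- short_fit(epochs = 5)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(coef(f1), coef(f2))
  f3 <- short_fit(epochs = 5, seed = 2)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("training does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(short_fit(epochs = 2)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("pure regression drives the data loss down", {
  tg <- tiny_tg(12, 4)
  fit <- pinn(tg$velocity, Re = 100,
              network = network_config(3, 24, "tanh", init_seed = 1),
              training = training_config(epochs = 80, minibatch = 4096,
                                         learning_rate = 1e-2, lr_decay = 1,
                                         lr_decay_every = 1000,
                                         sampling_seed = 7),
              weights = loss_weights(data = 100, eq = 0))
  h <- fit$history$data
  expect_lt(tail(h, 1), 0.1 * h[1])
  # non-increasing trend over smoothed checkpoints
  sm <- tapply(h, cut(seq_along(h), 4), mean)
  expect_true(all(diff(sm) < 0))
})

test_that("predictions are a pure function of the trained model", {
  tg <- tiny_tg(10, 3)
  fit <- short_fit(epochs = 3, tg = tg)
  p1 <- predict_field(fit, like = tg$velocity)
  p2 <- predict_field(fit, like = tg$velocity)
  expect_identical(p1$pressure$p, p2$pressure$p)
  # evaluation on a 2x finer grid restricts to the coarse evaluation
  fine_x <- seq(min(tg$velocity$x), max(tg$velocity$x),
                length.out = 2 * length(tg$velocity$x) - 1)
  pf <- predict_field(fit, x = fine_x, y = tg$velocity$y,
                      times = tg$velocity$t)
  iy <- seq(1, length(fine_x), by = 2)
  expect_equal(pf$velocity$u[iy, , ], p1$velocity$u, tolerance = 1e-12)
  # prediction at arbitrary points matches the grid evaluation
  pr <- predict(fit, data.frame(x = tg$velocity$x[2], y = tg$velocity$y[3],
                                t = tg$velocity$t[1]))
  expect_equal(pr$u, p1$velocity$u[2, 3, 1], tolerance = 1e-12)
})

test_that("predict_field masks body-interior nodes and declares its gauge", {
  tg <- tiny_tg(10, 3)
  fit <- short_fit(epochs = 2, tg = tg)
  kin <- square_kin(times = tg$velocity$t, half = 0.8, cx = pi, cy = pi)
  pf <- predict_field(fit, like = tg$velocity, kinematics = kin)
  expect_true(any(!pf$velocity$mask))
  expect_equal(pf$pressure$gauge, "zero_mean")
  expect_equal(mean(pf$pressure$p[pf$pressure$mask]), 0, tolerance = 1e-10)
  expect_error(predict_field(build_network(network_config(2, 8))),
               "untrained")
})

test_that("surface pressure is evaluated exactly on the contour", {
  tg <- tiny_tg(10, 3)
  fit <- short_fit(epochs = 2, tg = tg)
  kin <- square_kin(times = tg$velocity$t, half = 0.5, cx = pi, cy = pi)
  sp <- surface_pressure(fit, kin)
  expect_true(all(sp$extrap_dist == 0))
  # values equal direct network evaluation at the contour coordinates
  ct <- kin$contours[[1]]
  direct <- predict(fit, data.frame(x = ct$x, y = ct$y, t = kin$times[1]))$p
  sel <- sp$time == kin$times[1]
  expect_setequal(round(sp$p[sel], 12), round(direct, 12))
  expect_error(surface_pressure(fit, kin, times = 99), "undefined")
})

test_that("surface points are ordered nose-to-tail with consistent sides", {
  p <- carangiform_params()
  kin <- carangiform_kinematics(p, 20, times = 0)
  tg <- tiny_tg(10, 3)
  fit <- short_fit(epochs = 2, tg = tg)
  sp <- surface_pressure(fit, kin)
  for (s in c("left", "right"))
    expect_false(is.unsorted(sp$station[sp$side == s]))
  # left side has outward normals with positive mean y-component
  ct <- kin$contours[[1]]
  expect_gt(mean(ct$ny[ct$side == "left"]), 0)
  expect_lt(mean(ct$ny[ct$side == "right"]), 0)
})

test_that("divergent training aborts with a diagnostic", {
  tg <- tiny_tg(8, 3)
  expect_error(
    pinn(tg$velocity, Re = 100,
         network = network_config(2, 8, init_seed = 1),
         training = training_config(epochs = 50, minibatch = 512,
                                    learning_rate = 1e155, lr_decay = 1,
                                    lr_decay_every = 100, sampling_seed = 1)),
    "diverged")
})

test_that("configuration errors are caught before training", {
  tg <- tiny_tg(8, 3)
  expect_error(pinn(tg$velocity, Re = -5), "positive")
  expect_error(pinn(tg$velocity), "Re|scaling")
  expect_error(pinn(tg$velocity, Re = 10, bc = boundary_spec(body = TRUE)),
               "without kinematics")
  dimser <- structure(tg$velocity, units = "dimensional")
  expect_error(pinn(dimser, Re = 10), "non-dimensionalized")
})
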