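test_that("network construction is seeded and well shaped", {
  m1 <- tiny_net(seed = 5); m2 <- tiny_net(seed = 5); m3 <- tiny_net(seed = 6)
  X <- cbind(runif(20), runif(20), runif(20))
  expect_identical(mlp_evaluate(m1, X)$value, mlp_evaluate(m2, X)$value)
  expect_false(identical(mlp_evaluate(m1, X)$value,
                         mlp_evaluate(m3, X)$value))
  expect_equal(dim(mlp_evaluate(m1, X)$value), c(20L, 3L))
  # saturation-safe: finite outputs far outside the training domain
  Xbig <- as.matrix(expand.grid(x = c(-10, 10), y = c(-10, 10),
                                t = c(-10, 10)))
  for (act in c("sigmoid", "tanh"))
    expect_true(all(is.finite(
      mlp_evaluate(tiny_net(act = act), Xbig, deriv = 2)$value)))
  expect_error(network_config(0, 10), "at least one")
})

test_that("exact network derivatives match central finite differences", {
  # the derivative contract behind the momentum residuals: every first and
  # second derivative used in the residuals, at 100 random probe points
  set.seed(3)
  for (act in c("sigmoid", "tanh")) {
    m <- tiny_net(3, 16, act = act, seed = 2)
    X <- cbind(runif(100), runif(100), runif(100))
    ev <- mlp_evaluate(m, X, deriv = 2)
    h <- 1e-4
    shift <- function(col, dh) { Xs <- X; Xs[, col] <- Xs[, col] + dh; Xs }
    for (col in 1:3) {
      fd <- (mlp_evaluate(m, shift(col, h))$value -
             mlp_evaluate(m, shift(col, -h))$value) / (2 * h)
      an <- ev[[c("dx", "dy", "dt")[col]]]
      expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-5)
    }
    for (col in 1:2) {
      ch <- c("dx", "dy")[col]
      fd2 <- (mlp_evaluate(m, shift(col, h), deriv = 1)[[ch]] -
              mlp_evaluate(m, shift(col, -h), deriv = 1)[[ch]]) / (2 * h)
      an2 <- ev[[c("dxx", "dyy")[col]]]
      expect_lt(max(abs(fd2 - an2)) / max(abs(an2)), 1e-5)
    }
  }
})

test_that("data loss: exact fit, constant offset, and a loop oracle", {
  m <- constant_output_net(u0 = 0.3, v0 = -0.2)
  batch <- data.frame(x = runif(15), y = runif(15), t = runif(15),
                      u = 0.3, v = -0.2)
  expect_equal(data_loss(m, batch), 0)
  # constant offset delta in u only -> loss delta^2
  batch$u <- 0.3 - 0.05
  expect_equal(data_loss(m, batch), 0.05^2, tolerance = 1e-12)
  # random batch equals brute-force accumulation
  set.seed(9)
  m2 <- tiny_net(2, 10, seed = 4)
  b2 <- data.frame(x = runif(37), y = runif(37), t = runif(37),
                   u = rnorm(37), v = rnorm(37))
  pred <- mlp_evaluate(m2, as.matrix(b2[, 1:3]))$value
  acc <- 0
  for (i in 1:37)
    acc <- acc + (pred[i, 1] - b2$u[i])^2 + (pred[i, 2] - b2$v[i])^2
  expect_equal(data_loss(m2, b2), acc / 37, tolerance = 1e-12)
  expect_error(data_loss(m2, b2[0, ]), "empty")
})

test_that("momentum residuals vanish for constant fields and obey the oracle", {
  m <- constant_output_net(u0 = 0.7, v0 = -0.1, p0 = 2)
  X <- cbind(runif(25), runif(25), runif(25))
  r <- ns_residuals(m, X, Re = 50)
  expect_equal(max(abs(r$residuals)), 0, tolerance = 1e-12)
  expect_equal(r$loss, 0, tolerance = 1e-12)
  # residual assembly oracle from the evaluated derivatives
  m2 <- tiny_net(2, 12, seed = 8)
  r2 <- ns_residuals(m2, X, Re = 30, enforce_continuity = TRUE)
  ev <- mlp_evaluate(m2, X, deriv = 2)
  ex <- ev$dt[, 1] + ev$value[, 1] * ev$dx[, 1] + ev$value[, 2] * ev$dy[, 1] +
    ev$dx[, 3] - (ev$dxx[, 1] + ev$dyy[, 1]) / 30
  expect_equal(r2$residuals[, "ex"], ex, tolerance = 1e-12)
  expect_equal(r2$residuals[, "ec"], ev$dx[, 1] + ev$dy[, 2],
               tolerance = 1e-12)
  expect_equal(r2$loss, sum(colMeans(r2$residuals^2)), tolerance = 1e-12)
  expect_error(ns_residuals(m2, X, Re = -1), "positive")
})

test_that("boundary losses: non-penetration, pressure edges, inlet", {
  kin <- square_kin()
  ct <- kin$contours[[1]]
  body <- data.frame(x = ct$x, y = ct$y, t = 0, nx = ct$nx, ny = ct$ny,
                     un = ct$un)
  # a rigid, non-moving body and a zero-velocity model: body term 0
  m0 <- constant_output_net(0, 0, 5)
  bl <- boundary_losses(m0, body = body)
  expect_equal(unname(bl["body"]), 0, tolerance = 1e-14)
  # pressure edge with p == c gives c^2
  edge <- data.frame(x = runif(10), y = 1, t = runif(10))
  expect_equal(unname(boundary_losses(m0, pressure_edges = edge)["pressure"]),
               25, tolerance = 1e-10)
  # inlet mismatch
  inl <- data.frame(x = 0, y = runif(8), t = runif(8), u = 1, v = 0)
  expect_equal(unname(boundary_losses(m0, inlet = inl)["inlet"]), 1,
               tolerance = 1e-12)
  # body term equals the brute-force sum over sampled points
  m2 <- tiny_net(2, 10, seed = 11)
  pred <- mlp_evaluate(m2, as.matrix(body[, 1:3]))$value
  acc <- mean((pred[, 1] * body$nx + pred[, 2] * body$ny - body$un)^2)
  expect_equal(unname(boundary_losses(m2, body = body)["body"]), acc,
               tolerance = 1e-12)
  expect_error(boundary_losses(m2), "no boundary batch")
})

test_that("composite loss weights and decomposes as declared", {
  m <- tiny_net(2, 10, seed = 3)
  set.seed(1)
  batches <- list(
    data = data.frame(x = runif(9), y = runif(9), t = runif(9),
                      u = rnorm(9), v = rnorm(9)),
    eq = data.frame(x = runif(11), y = runif(11), t = runif(11)))
  kin <- square_kin(); ct <- kin$contours[[1]]
  batches$body <- data.frame(x = ct$x, y = ct$y, t = 0, nx = ct$nx,
                             ny = ct$ny, un = ct$un)
  zero <- total_loss(m, batches, loss_weights(0, 0, 0, 0), Re = 10)
  expect_equal(zero$total, 0)
  tl <- total_loss(m, batches, loss_weights(), Re = 10)
  a <- data_loss(m, batches$data)
  b <- unname(boundary_losses(m, body = batches$body)["total"])
  cc <- ns_residuals(m, batches$eq, Re = 10)$loss
  expect_equal(tl$total, 100 * a + 100 * b + cc, tolerance = 1e-12)
  expect_equal(unname(tl$terms["data"] * 100 + tl$terms["bc"] * 100 +
                 tl$terms["eq"]), tl$total, tolerance = 1e-12)
  expect_error(loss_weights(data = -1), "nonnegative")
})

test_that("gauge property: with no pressure term active, a pressure offset
           leaves every loss unchanged", {
  m <- tiny_net(2, 10, seed = 3)
  m_shift <- m
  m_shift$theta[length(m$theta)] <- m$theta[length(m$theta)] + 3.7
  set.seed(2)
  batches <- list(
    data = data.frame(x = runif(9), y = runif(9), t = runif(9),
                      u = rnorm(9), v = rnorm(9)),
    eq = data.frame(x = runif(11), y = runif(11), t = runif(11)))
  kin <- square_kin(); ct <- kin$contours[[1]]
  batches$body <- data.frame(x = ct$x, y = ct$y, t = 0, nx = ct$nx,
                             ny = ct$ny, un = ct$un)
  t1 <- total_loss(m, batches, loss_weights(), Re = 10)
  t2 <- total_loss(m_shift, batches, loss_weights(), Re = 10)
  expect_equal(t1$total, t2$total, tolerance = 1e-10)
  # predicted pressures really differ by the constant
  X <- cbind(0.5, 0.5, 0.5)
  expect_equal(mlp_evaluate(m_shift, X)$value[, 3] -
                 mlp_evaluate(m, X)$value[, 3], 3.7, tolerance = 1e-12)
})
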