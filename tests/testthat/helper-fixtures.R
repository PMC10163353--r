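# Shared small fixtures, built in code at load time.

tiny_tg <- function(n = 16, nt = 5, Re = 100)
  taylor_green_truth(n, n, times = seq(0, 0.2, length.out = nt), Re = Re)

tiny_series <- function(nx = 4, ny = 4, nt = 3) {
  dims <- c(nx, ny, nt)
  velocity_series(seq(0, 1, length.out = nx), seq(0, 1, length.out = ny),
                  seq(0, 1, length.out = nt),
                  array(seq_len(prod(dims)) / prod(dims), dims),
                  array(-seq_len(prod(dims)) / prod(dims), dims))
}

tiny_net <- function(layers = 2, neurons = 8, act = "sigmoid", gain = TRUE,
                     seed = 1) {
  build_network(network_config(layers, neurons, act, gain = gain,
                               init_seed = seed),
                domain = list(x = c(0, 1), y = c(0, 1), t = c(0, 1)))
}

# a network whose (u, v, p) outputs are constant: zero the output-layer
# weights and set its bias
constant_output_net <- function(u0 = 0, v0 = 0, p0 = 0, ...) {
  m <- tiny_net(...)
  n <- length(m$theta)
  m$theta[(n - 2):n] <- c(u0, v0, p0)   # output bias
  nh <- m$arch$sizes[length(m$arch$sizes)]
  m$theta[(n - 3 - 3 * nh + 1):(n - 3)] <- 0  # output weights
  m
}

square_kin <- function(times = 0, half = 0.25, cx = 0.5, cy = 0.5,
                       u = 0, v = 0) {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  body_kinematics(times, lapply(times, function(t)
    data.frame(x = cx + half * cos(th), y = cy + half * sin(th),
               u = u, v = v)))
}

expect_series_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$x, b$x, tolerance = tol)
  expect_equal(a$y, b$y, tolerance = tol)
  expect_equal(a$t, b$t, tolerance = tol)
  expect_equal(a$mask, b$mask)
  for (f in intersect(c("u", "v", "p"), names(a)))
    expect_equal(a[[f]][a$mask], b[[f]][b$mask], tolerance = tol)
}
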