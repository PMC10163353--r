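#' Network architecture configuration
#'
#' The coordinate network maps `(x, y, t)` to `(u, v, p)` through fully
#' connected hidden layers. Each hidden layer applies an affine map followed
#' by the activation and a per-neuron trainable gain ("gamma") vector;
#' `gain = FALSE` switches to plain affine layers. Defaults follow the
#' reference configuration: 12 hidden layers of 120 neurons with sigmoid
#' activation. Desk-scale presets used in examples and tests are much
#' smaller (see [training_config()]).
#'
#' @param n_hidden_layers number of hidden layers
#' @param neurons_per_layer neurons in each hidden layer
#' @param activation `"sigmoid"` or `"tanh"`
#' @param gain use per-neuron trainable gain vectors in hidden layers
#' @param init_seed integer seed for the deterministic parameter
#'   initialization (Glorot-uniform weights, zero biases, unit gains)
#' @return an object of class `"network_config"`
#' @export
network_config <- function(n_hidden_layers = 12, neurons_per_layer = 120,
                           activation = c("sigmoid", "tanh"), gain = TRUE,
                           init_seed = 1L) {
  activation <- match.arg(activation)
  if (n_hidden_layers < 1 || neurons_per_layer < 1)
    stop("network must have at least one layer and one neuron")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 neurons_per_layer = as.integer(neurons_per_layer),
                 activation = activation, gain = isTRUE(gain),
                 init_seed = as.integer(init_seed)),
            class = "network_config")
}

#' Loss-term weights
#'
#' Weights of the four composite-loss terms: measured-data misfit, initial
#' conditions, boundary conditions, and governing-equation residuals. The
#' defaults (100, 0, 100, 1) are the reference configuration: the initial
#' condition term is retained in the loss structure but disabled by default.
#'
#' @param data,ic,bc,eq nonnegative weights
#' @return an object of class `"loss_weights"`
#' @export
loss_weights <- function(data = 100, ic = 0, bc = 100, eq = 1) {
  w <- c(data = data, ic = ic, bc = bc, eq = eq)
  if (any(w < 0)) stop("loss weights must be nonnegative")
  structure(as.list(w), class = "loss_weights")
}

#' Training configuration
#'
#' ADAM-based minibatch training. An epoch is one full pass over the
#' measured data points in random minibatches; the equation and boundary
#' batches are independent random subsets, each capped at `minibatch`
#' points per iteration. Reference defaults are 1500 epochs with minibatch
#' 10000; desk-scale runs use far fewer (see `pinn_preset()`).
#'
#' @param epochs passes over the data set
#' @param minibatch maximum points per loss term per iteration
#' @param learning_rate initial ADAM step size
#' @param lr_decay multiplicative decay factor
#' @param lr_decay_every apply the decay every this many epochs
#' @param sampling_seed integer seed for minibatch sampling
#' @param enforce_continuity include the divergence-free residual (off by
#'   default: with a 2D slice of a 3D flow the in-plane divergence is not
#'   expected to vanish)
#' @param checkpoint_every store a parameter snapshot every this many
#'   epochs (0 = none); used for convergence diagnostics
#' @return an object of class `"training_config"`
#' @export
training_config <- function(epochs = 1500, minibatch = 10000,
                            learning_rate = 1e-3, lr_decay = 0.5,
                            lr_decay_every = 500, sampling_seed = 1L,
                            enforce_continuity = FALSE,
                            checkpoint_every = 0) {
  if (epochs < 1 || minibatch < 1) stop("epochs and minibatch must be >= 1")
  if (learning_rate <= 0) stop("learning rate must be positive")
  structure(list(epochs = as.integer(epochs), minibatch = as.integer(minibatch),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 sampling_seed = as.integer(sampling_seed),
                 enforce_continuity = isTRUE(enforce_continuity),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "training_config")
}

#' External boundary conditions and body-condition switch
#'
#' Declares the condition applied on each external edge of the rectangular
#' domain (`"none"`, `"zero_pressure"`, or `"inlet_velocity"`) and whether
#' the non-penetration condition on the body surface is active. Inlet
#' values must be given exactly for edges of kind `"inlet_velocity"`.
#'
#' @param left,right,top,bottom edge condition kinds
#' @param body enforce the non-penetration condition on the body surface
#' @param u_in,v_in inlet velocity components (required iff some edge is an
#'   inlet)
#' @return an object of class `"boundary_spec"`
#' @export
boundary_spec <- function(left = "none", right = "none", top = "none",
                          bottom = "none", body = TRUE,
                          u_in = NULL, v_in = NULL) {
  kinds <- c("none", "zero_pressure", "inlet_velocity")
  edges <- list(left = match.arg(left, kinds), right = match.arg(right, kinds),
                top = match.arg(top, kinds), bottom = match.arg(bottom, kinds))
  has_inlet <- any(vapply(edges, identical, TRUE, "inlet_velocity"))
  if (has_inlet && (is.null(u_in) || is.null(v_in)))
    stop("inlet_velocity edge requires u_in and v_in")
  if (!has_inlet && (!is.null(u_in) || !is.null(v_in)))
    stop("inlet values given but no edge has kind inlet_velocity")
  structure(c(edges, list(body = isTRUE(body), u_in = u_in, v_in = v_in)),
            class = "boundary_spec")
}

# internal: architecture descriptor for the C++ core
pinn_arch <- function(config, domain) {
  list(sizes = rep(config$neurons_per_layer, config$n_hidden_layers),
       gain = config$gain,
       act = if (config$activation == "sigmoid") 0L else 1L,
       center = vapply(domain, mean, 0),
       scale = vapply(domain, function(r) max(diff(r) / 2, 1e-12), 0))
}

#' Build an untrained coordinate network
#'
#' Constructs the `(x, y, t) -> (u, v, p)` network with deterministic
#' Glorot-uniform initialization under the configured seed. Inputs are
#' affinely normalized to `[-1, 1]` over the given domain before entering
#' the first layer (the normalization is part of the model and is chained
#' through all reported derivatives).
#'
#' @param config a [network_config()]
#' @param domain list with components `x`, `y`, `t`, each a range `c(lo, hi)`
#' @return an object of class `"pinn"` (untrained)
#' @export
build_network <- function(config = network_config(),
                          domain = list(x = c(0, 1), y = c(0, 1), t = c(0, 1))) {
  stopifnot(inherits(config, "network_config"))
  arch <- pinn_arch(config, domain)
  len <- cpp_theta_length(arch$sizes, arch$gain)
  theta <- with_local_seed(config$init_seed, {
    sizes <- c(3L, arch$sizes, 3L)
    parts <- list()
    for (k in seq_len(length(sizes) - 1)) {
      m <- sizes[k]; n <- sizes[k + 1]
      lim <- sqrt(6 / (m + n))
      parts[[length(parts) + 1]] <- runif(n * m, -lim, lim)   # W
      parts[[length(parts) + 1]] <- rep(0, n)                 # b
      hidden <- k < length(sizes) - 1
      if (hidden && arch$gain) parts[[length(parts) + 1]] <- rep(1, n)
    }
    unlist(parts)
  })
  stopifnot(length(theta) == len)
  structure(list(theta = theta, arch = arch, network = config,
                 domain = domain, trained = FALSE, history = NULL),
            class = "pinn")
}

#' Evaluate the network and its exact coordinate derivatives
#'
#' Evaluates `(u, v, p)` and, on request, the exact first derivatives with
#' respect to `x`, `y`, `t` and the second derivatives with respect to `x`
#' and `y`, all propagated analytically through the network (no finite
#' differencing).
#'
#' @param model a `"pinn"` object
#' @param X numeric matrix or data frame with columns `x`, `y`, `t`
#' @param deriv 0 (values only), 1 (+ first derivatives) or 2 (+ second)
#' @return list of `n x 3` matrices (`value`, and per requested order `dx`,
#'   `dy`, `dt`, `dxx`, `dyy`); columns are `(u, v, p)`
#' @export
mlp_evaluate <- function(model, X, deriv = 0) {
  stopifnot(inherits(model, "pinn"))
  X <- as_xyt(X)
  cpp_mlp_eval(model$theta, model$arch, X, as.integer(deriv))
}

as_xyt <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X[, c("x", "y", "t")])
  if (!is.matrix(X) || ncol(X) != 3) stop("expected columns x, y, t")
  storage.mode(X) <- "double"
  unname(X)
}

#' Measured-data loss
#'
#' Mean squared discrepancy between predicted and measured velocities,
#' summed over the two components: `mean((u_pred - u)^2) +
#' mean((v_pred - v)^2)` over the batch.
#'
#' @param model a `"pinn"` object
#' @param batch data frame with columns `x`, `y`, `t`, `u`, `v`
#' @return scalar loss
#' @export
data_loss <- function(model, batch) {
  if (NROW(batch) == 0) stop("empty batch")
  ob <- cpp_pinn_obj(model$theta, model$arch,
                     list(data = list(X = as_xyt(batch), u = batch$u, v = batch$v)),
                     c(1, 0, 0, 0), Re = 1, continuity = FALSE, want_grad = FALSE)
  unname(ob$terms["data"])
}

#' Navier-Stokes momentum residuals of the network
#'
#' Residuals of the two non-dimensional momentum equations evaluated by
#' exact differentiation of the network at arbitrary collocation points:
#' `e_x = u_t + u u_x + v u_y + p_x - (u_xx + u_yy)/Re` and likewise for
#' `e_y`; the in-plane continuity residual `u_x + v_y` is appended only when
#' `enforce_continuity` is `TRUE`. The loss is the mean of squared
#' residuals (summed over the active residual components).
#'
#' @param model a `"pinn"` object
#' @param X collocation points (matrix or data frame with `x`, `y`, `t`)
#' @param Re Reynolds number (> 0)
#' @param enforce_continuity include the continuity residual
#' @return list with `residuals` (one column per active residual) and
#'   scalar `loss`
#' @export
ns_residuals <- function(model, X, Re, enforce_continuity = FALSE) {
  if (Re <= 0) stop("Re must be positive")
  X <- as_xyt(X)
  ev <- cpp_mlp_eval(model$theta, model$arch, X, 2L)
  u <- ev$value[, 1]; v <- ev$value[, 2]
  ex <- ev$dt[, 1] + u * ev$dx[, 1] + v * ev$dy[, 1] + ev$dx[, 3] -
    (ev$dxx[, 1] + ev$dyy[, 1]) / Re
  ey <- ev$dt[, 2] + u * ev$dx[, 2] + v * ev$dy[, 2] + ev$dy[, 3] -
    (ev$dxx[, 2] + ev$dyy[, 2]) / Re
  res <- cbind(ex = ex, ey = ey)
  if (enforce_continuity) res <- cbind(res, ec = ev$dx[, 1] + ev$dy[, 2])
  list(residuals = res, loss = sum(colMeans(res^2)))
}

#' Boundary-condition losses
#'
#' The three boundary loss terms: the non-penetration condition on the body
#' surface (mean squared mismatch between the predicted velocity projected
#' on the outward normal and the measured normal velocity `u_n`), the
#' zero-pressure condition on external edges (mean squared predicted
#' pressure), and the inlet-velocity condition (mean squared velocity
#' mismatch). Terms whose batch is `NULL` contribute zero.
#'
#' @param model a `"pinn"` object
#' @param body data frame with `x`, `y`, `t`, `nx`, `ny`, `un`
#' @param pressure_edges data frame with `x`, `y`, `t`
#' @param inlet data frame with `x`, `y`, `t`, `u`, `v`
#' @return named vector with components `body`, `pressure`, `inlet` and
#'   their sum `total`
#' @export
boundary_losses <- function(model, body = NULL, pressure_edges = NULL,
                            inlet = NULL) {
  batches <- list()
  if (!is.null(body))
    batches$body <- list(X = as_xyt(body), nx = body$nx, ny = body$ny,
                         un = body$un)
  if (!is.null(pressure_edges))
    batches$pedge <- list(X = as_xyt(pressure_edges))
  if (!is.null(inlet))
    batches$inlet <- list(X = as_xyt(inlet), u = inlet$u, v = inlet$v)
  if (length(batches) == 0) stop("no boundary batch supplied")
  ob <- cpp_pinn_obj(model$theta, model$arch, batches, c(0, 0, 1, 0),
                     Re = 1, continuity = FALSE, want_grad = FALSE)
  c(body = unname(ob$terms["bc_body"]),
    pressure = unname(ob$terms["bc_pressure"]),
    inlet = unname(ob$terms["bc_inlet"]),
    total = unname(ob$terms["bc"]))
}

#' Composite training loss
#'
#' Weighted sum `w_data * L_data + w_ic * L_ic + w_bc * L_bc + w_eq * L_eq`
#' with the per-term breakdown.
#'
#' @param model a `"pinn"` object
#' @param batches named list with optional elements `data`, `ic` (data
#'   frames with `x,y,t,u,v`), `body`, `pressure_edges`, `inlet` (see
#'   [boundary_losses()]) and `eq` (collocation points)
#' @param weights a [loss_weights()]
#' @param Re Reynolds number (needed when an `eq` batch is present)
#' @param enforce_continuity include the continuity residual in `L_eq`
#' @return list with `total` and named `terms`
#' @export
total_loss <- function(model, batches, weights = loss_weights(), Re = NULL,
                       enforce_continuity = FALSE) {
  stopifnot(inherits(weights, "loss_weights"))
  bt <- list()
  add_vel <- function(b) list(X = as_xyt(b), u = b$u, v = b$v)
  if (!is.null(batches$data)) bt$data <- add_vel(batches$data)
  if (!is.null(batches$ic)) bt$ic <- add_vel(batches$ic)
  if (!is.null(batches$body))
    bt$body <- list(X = as_xyt(batches$body), nx = batches$body$nx,
                    ny = batches$body$ny, un = batches$body$un)
  if (!is.null(batches$pressure_edges))
    bt$pedge <- list(X = as_xyt(batches$pressure_edges))
  if (!is.null(batches$inlet)) bt$inlet <- add_vel(batches$inlet)
  if (!is.null(batches$eq)) {
    if (is.null(Re)) stop("Re required for the equation residual term")
    bt$eq <- list(X = as_xyt(batches$eq))
  }
  lam <- c(weights$data, weights$ic, weights$bc, weights$eq)
  ob <- cpp_pinn_obj(model$theta, model$arch, bt, lam,
                     Re = if (is.null(Re)) 1 else Re,
                     continuity = enforce_continuity, want_grad = FALSE)
  list(total = ob$loss, terms = ob$terms)
}
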