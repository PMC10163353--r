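#' Fit a physics-informed neural network pressure reconstruction
#'
#' Trains a coordinate network `(x, y, t) -> (u, v, p)` so that it
#' simultaneously fits the measured velocity field, satisfies the
#' non-dimensional Navier-Stokes momentum residuals at collocation points,
#' and honors the declared boundary conditions (including the
#' non-penetration condition on a moving body surface). The pressure output
#' of the trained network is the reconstruction; it can be evaluated
#' anywhere in the domain, in particular exactly on the body contour
#' ([surface_pressure()]), with no extrapolation.
#'
#' Training uses ADAM with minibatches: one epoch is a full pass over the
#' measured velocity vectors in random minibatches; the equation and
#' boundary batches are independent random subsets per iteration, each
#' capped at the configured minibatch size. The run is fully reproducible
#' from the two seeds (parameter initialization and sampling).
#'
#' @param velocity a non-dimensional [velocity_series()] of measurements;
#'   masked (body-interior) nodes are never sampled
#' @param kinematics optional [body_kinematics()]; required when the body
#'   boundary condition is active and used to exclude body-interior
#'   collocation points
#' @param bc a [boundary_spec()]; the default enforces the body condition
#'   iff `kinematics` is supplied and leaves external edges free
#' @param Re Reynolds number; defaults to the `scaling_set` attached to
#'   `velocity`
#' @param network a [network_config()]
#' @param training a [training_config()]
#' @param weights a [loss_weights()]
#' @param collocation points where the momentum residuals are evaluated:
#'   `NULL` (the measurement grid), a list with vectors `x`, `y`, `t` (a
#'   finer grid, the recommended choice when the measurements are coarse),
#'   or a matrix/data frame of points. Body-interior points are excluded
#'   per time step when `kinematics` is given.
#' @param verbose print per-epoch losses
#' @return an object of class `"pinn"` with the trained parameters, the
#'   per-epoch loss history (`$history`), optional checkpoints and all
#'   configuration needed to reproduce the run
#' @seealso [predict.pinn()], [predict_field()], [surface_pressure()],
#'   [ns_residuals()]
#' @export
pinn <- function(velocity, kinematics = NULL,
                 bc = boundary_spec(body = !is.null(kinematics)),
                 Re = NULL, network = network_config(),
                 training = training_config(), weights = loss_weights(),
                 collocation = NULL, verbose = FALSE) {
  stopifnot(inherits(velocity, "velocity_series"),
            inherits(bc, "boundary_spec"),
            inherits(network, "network_config"),
            inherits(training, "training_config"),
            inherits(weights, "loss_weights"))
  if (is_dimensional(velocity))
    stop("velocity series must be non-dimensionalized before training")
  if (is.null(Re)) {
    sc <- attr(velocity, "scaling")
    if (is.null(sc)) stop("supply Re or attach a scaling_set to the series")
    Re <- sc$Re
  }
  if (Re <= 0) stop("Re must be positive")
  if (bc$body && is.null(kinematics))
    stop("body boundary condition requested without kinematics")

  # measured-data points
  ok <- which(velocity$mask)
  if (length(ok) == 0) stop("empty dataset: no valid velocity vectors")
  Xd <- series_points(velocity, valid_only = TRUE)
  ud <- velocity$u[ok]; vd <- velocity$v[ok]

  # collocation points for the momentum residuals; when the body kinematics
  # are known, the contour points are appended so the residuals pin the
  # pressure gradient right up to the fluid-body interface (the governing
  # equations hold there even though no vectors are measured)
  Xe <- build_collocation(velocity, collocation, kinematics)
  if (!is.null(kinematics)) {
    Xs <- do.call(rbind, lapply(seq_along(kinematics$times), function(it) {
      ct <- kinematics$contours[[it]]
      cbind(ct$x, ct$y, kinematics$times[it])
    }))
    Xe <- rbind(Xe, unname(Xs))
  }

  # boundary batches
  bb <- build_boundary_batches(velocity, kinematics, bc)

  domain <- list(x = range(velocity$x), y = range(velocity$y),
                 t = range(velocity$t))
  model <- build_network(network, domain)
  lam <- c(weights$data, weights$ic, weights$bc, weights$eq)

  nd <- nrow(Xd); ne <- nrow(Xe)
  mb <- training$minibatch
  iters_per_epoch <- max(1L, ceiling(nd / mb))
  theta <- model$theta
  madam <- numeric(length(theta)); vadam <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist_rows <- vector("list", training$epochs)
  checkpoints <- list()

  with_local_seed(training$sampling_seed, {
    for (epoch in seq_len(training$epochs)) {
      lr <- training$learning_rate *
        training$lr_decay^((epoch - 1) %/% training$lr_decay_every)
      perm <- sample.int(nd)
      acc <- NULL
      for (it in seq_len(iters_per_epoch)) {
        idx <- perm[((it - 1) * mb + 1):min(it * mb, nd)]
        batches <- list(data = list(X = Xd[idx, , drop = FALSE],
                                    u = ud[idx], v = vd[idx]))
        eidx <- if (ne > mb) sample.int(ne, mb) else seq_len(ne)
        batches$eq <- list(X = Xe[eidx, , drop = FALSE])
        batches <- c(batches, sample_boundary(bb, mb))
        ob <- cpp_pinn_obj(theta, model$arch, batches, lam, Re,
                           training$enforce_continuity, TRUE)
        if (!is.finite(ob$loss))
          stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
        step <- step + 1L
        madam <- beta1 * madam + (1 - beta1) * ob$grad
        vadam <- beta2 * vadam + (1 - beta2) * ob$grad^2
        mhat <- madam / (1 - beta1^step)
        vhat <- vadam / (1 - beta2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
        acc <- if (is.null(acc)) c(loss = ob$loss, ob$terms) else
          acc + c(loss = ob$loss, ob$terms)
      }
      acc <- acc / iters_per_epoch
      hist_rows[[epoch]] <- data.frame(epoch = epoch, loss = acc[["loss"]],
                                       data = acc[["data"]], bc = acc[["bc"]],
                                       eq = acc[["eq"]], lr = lr)
      if (training$checkpoint_every > 0 &&
          epoch %% training$checkpoint_every == 0)
        checkpoints[[length(checkpoints) + 1]] <-
          list(epoch = epoch, theta = theta)
      if (verbose)
        message(sprintf("epoch %4d  loss %.4g  data %.4g  bc %.4g  eq %.4g",
                        epoch, acc[["loss"]], acc[["data"]], acc[["bc"]],
                        acc[["eq"]]))
    }
  })

  model$theta <- theta
  model$trained <- TRUE
  model$history <- do.call(rbind, hist_rows)
  model$checkpoints <- checkpoints
  model$Re <- Re
  model$bc <- bc
  model$weights <- weights
  model$training <- training
  model$gauge <- if (any(vapply(c("left", "right", "top", "bottom"),
                                function(e) identical(bc[[e]], "zero_pressure"),
                                TRUE))) "zero_at_boundary" else "zero_mean"
  model$n_data <- nd
  model$n_collocation <- ne
  model$call <- match.call()
  model
}

build_collocation <- function(velocity, collocation, kinematics) {
  if (is.null(collocation)) {
    grid <- list(x = velocity$x, y = velocity$y, t = velocity$t)
  } else if (is.list(collocation) && !is.data.frame(collocation) &&
             all(c("x", "y", "t") %in% names(collocation))) {
    grid <- collocation
  } else {
    return(exclude_body(as_xyt(collocation), kinematics))
  }
  pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, t = grid$t,
                               KEEP.OUT.ATTRS = FALSE))
  exclude_body(pts, kinematics)
}

exclude_body <- function(pts, kinematics) {
  if (is.null(kinematics)) return(pts)
  keep <- rep(TRUE, nrow(pts))
  for (tt in unique(pts[, 3])) {
    sel <- pts[, 3] == tt
    ct <- tryCatch(contour_at(kinematics, tt), error = function(e) NULL)
    if (is.null(ct)) next
    keep[sel] <- !point_in_polygon(pts[sel, 1], pts[sel, 2], ct$x, ct$y)
  }
  pts[keep, , drop = FALSE]
}

build_boundary_batches <- function(velocity, kinematics, bc) {
  out <- list()
  if (bc$body && !is.null(kinematics)) {
    rows <- do.call(rbind, lapply(seq_along(kinematics$times), function(it) {
      ct <- kinematics$contours[[it]]
      cbind(x = ct$x, y = ct$y, t = kinematics$times[it],
            nx = ct$nx, ny = ct$ny, un = ct$un)
    }))
    out$body <- list(X = rows[, 1:3, drop = FALSE], nx = rows[, "nx"],
                     ny = rows[, "ny"], un = rows[, "un"])
  }
  edge_pts <- function(edge) {
    switch(edge,
      left = cbind(x = velocity$x[1], y = velocity$y, t = 0),
      right = cbind(x = velocity$x[length(velocity$x)], y = velocity$y, t = 0),
      bottom = cbind(x = velocity$x, y = velocity$y[1], t = 0),
      top = cbind(x = velocity$x, y = velocity$y[length(velocity$y)], t = 0))
  }
  all_times <- function(pts) {
    do.call(rbind, lapply(velocity$t, function(tt) {
      pts[, 3] <- tt; pts
    }))
  }
  pe <- NULL; inl <- NULL
  for (edge in c("left", "right", "top", "bottom")) {
    if (identical(bc[[edge]], "zero_pressure"))
      pe <- rbind(pe, all_times(edge_pts(edge)))
    if (identical(bc[[edge]], "inlet_velocity"))
      inl <- rbind(inl, all_times(edge_pts(edge)))
  }
  if (!is.null(pe)) out$pedge <- list(X = unname(pe))
  if (!is.null(inl))
    out$inlet <- list(X = unname(inl), u = rep(bc$u_in, nrow(inl)),
                      v = rep(bc$v_in, nrow(inl)))
  out
}

sample_boundary <- function(bb, mb) {
  out <- list()
  for (nm in names(bb)) {
    b <- bb[[nm]]
    n <- nrow(b$X)
    idx <- if (n > mb) sample.int(n, mb) else seq_len(n)
    out[[nm]] <- lapply(b, function(el)
      if (is.matrix(el)) el[idx, , drop = FALSE] else el[idx])
  }
  out
}

#' @export
print.pinn <- function(x, ...) {
  cat("Physics-informed pressure reconstruction network\n")
  cat(sprintf("  architecture: %d x %d (%s%s), %d parameters\n",
              x$network$n_hidden_layers, x$network$neurons_per_layer,
              x$network$activation, if (x$network$gain) ", gained" else "",
              length(x$theta)))
  if (x$trained) {
    h <- tail(x$history, 1)
    cat(sprintf("  trained: %d epochs, final loss %.4g (data %.4g, bc %.4g, eq %.4g)\n",
                nrow(x$history), h$loss, h$data, h$bc, h$eq))
    cat(sprintf("  Re = %g, gauge = %s\n", x$Re, x$gauge))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.pinn <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat(sprintf("  %d data points, %d collocation points\n",
                object$n_data, object$n_collocation))
    cat("  loss history (epoch quartiles):\n")
    print(object$history[unique(round(quantile(seq_len(nrow(object$history))))),
                         c("epoch", "loss", "data", "bc", "eq")],
          row.names = FALSE)
  }
  invisible(object)
}

#' @importFrom stats quantile
#' @export
coef.pinn <- function(object, ...) object$theta

#' Predict velocity and pressure at arbitrary coordinates
#'
#' @param object a trained `"pinn"`
#' @param newdata data frame or matrix with columns `x`, `y`, `t`
#' @param ... unused
#' @return data frame with columns `u`, `v`, `p`
#' @export
predict.pinn <- function(object, newdata, ...) {
  ev <- mlp_evaluate(object, newdata, deriv = 0)
  data.frame(u = ev$value[, 1], v = ev$value[, 2], p = ev$value[, 3])
}

#' Residuals of a fitted reconstruction
#'
#' @param object a trained `"pinn"`
#' @param newdata points at which to evaluate (`x`, `y`, `t`; for
#'   `type = "data"` also `u`, `v`)
#' @param type `"momentum"` for the Navier-Stokes residuals,
#'   `"data"` for velocity misfits
#' @param ... unused
#' @return matrix of residuals
#' @export
residuals.pinn <- function(object, newdata, type = c("momentum", "data"), ...) {
  type <- match.arg(type)
  if (type == "momentum")
    return(ns_residuals(object, newdata, object$Re,
                        object$training$enforce_continuity)$residuals)
  pr <- predict(object, newdata)
  cbind(du = pr$u - newdata$u, dv = pr$v - newdata$v)
}

#' Plot the training-loss history
#'
#' @param x a trained `"pinn"`
#' @param ... passed to [graphics::matplot()]
#' @importFrom graphics matplot legend
#' @export
plot.pinn <- function(x, ...) {
  if (is.null(x$history)) stop("untrained model")
  h <- x$history
  matplot(h$epoch, cbind(h$loss, h$data, h$bc, h$eq), type = "l", log = "y",
          lty = 1, xlab = "epoch", ylab = "loss", ...)
  legend("topright", c("total", "data", "bc", "eq"), lty = 1, col = 1:4,
         bty = "n")
  invisible(x)
}

#' Dense field evaluation of a trained reconstruction
#'
#' Evaluates the network on an arbitrary grid (which may be finer than the
#' measurement grid). If the model was trained with a zero-pressure edge
#' condition the pressure gauge is `zero_at_boundary`; otherwise the
#' pressure is only determined up to a constant and the `zero_mean` gauge is
#' applied over the valid nodes.
#'
#' @param model a trained `"pinn"`
#' @param x,y,times grid axes (default: reuse a series' axes via `like`)
#' @param like optional [velocity_series()] providing the axes
#' @param kinematics optional [body_kinematics()] used to mask body-interior
#'   nodes in the output
#' @return list with `velocity` and `pressure` series
#' @export
predict_field <- function(model, x = NULL, y = NULL, times = NULL,
                          like = NULL, kinematics = NULL) {
  stopifnot(inherits(model, "pinn"))
  if (!model$trained) stop("untrained model")
  if (!is.null(like)) {
    x <- x %||% like$x; y <- y %||% like$y; times <- times %||% like$t
  }
  if (is.null(x) || is.null(y) || is.null(times))
    stop("supply grid axes or a series via 'like'")
  pts <- as.matrix(expand.grid(x = x, y = y, t = times,
                               KEEP.OUT.ATTRS = FALSE))
  ev <- cpp_mlp_eval(model$theta, model$arch, unname(pts), 0L)
  dims <- c(length(x), length(y), length(times))
  u <- array(ev$value[, 1], dims)
  v <- array(ev$value[, 2], dims)
  p <- array(ev$value[, 3], dims)
  vel <- velocity_series(x, y, times, u, v)
  if (!is.null(kinematics)) vel <- mask_body_interior(vel, kinematics)
  gauge <- model$gauge %||% "zero_mean"
  shift <- 0
  if (gauge == "zero_mean") {
    shift <- -mean(p[vel$mask])
    p <- p + shift
  }
  pres <- pressure_series(x, y, times, p, gauge = gauge, mask = vel$mask)
  # constant added to the raw network pressure; add the same shift to raw
  # surface_pressure() values to place them in this series' gauge
  attr(pres, "gauge_shift") <- shift
  list(velocity = vel, pressure = pres)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surface pressure evaluated directly on the body contour
#'
#' The trained network is evaluated exactly at the contour coordinates --
#' the extrapolation distance is identically zero, in contrast to
#' grid-based baselines which must copy the nearest valid grid node
#' ([nearest_point_surface_pressure()]). Points are ordered nose-to-tail on
#' each side.
#'
#' @param model a trained `"pinn"`
#' @param kinematics a [body_kinematics()]
#' @param times times at which to evaluate (default: all kinematics times);
#'   must lie within the training window
#' @param scaling optional [scaling_set()]; when given, a pressure
#'   coefficient column `Cp = p / (rho U^2 / 2)` is added
#' @return data frame with columns `time`, `station`, `side`, `x`, `y`,
#'   `p`, `extrap_dist` (always 0), ordered nose-to-tail within side
#' @export
surface_pressure <- function(model, kinematics, times = NULL, scaling = NULL) {
  stopifnot(inherits(model, "pinn"), inherits(kinematics, "body_kinematics"))
  if (!model$trained) stop("untrained model")
  times <- times %||% kinematics$times
  out <- do.call(rbind, lapply(times, function(tt) {
    ct <- contour_at(kinematics, tt)
    ev <- cpp_mlp_eval(model$theta, model$arch,
                       cbind(ct$x, ct$y, tt), 0L)
    df <- data.frame(time = tt,
                     station = if (!is.null(ct$station)) ct$station else NA,
                     side = if (!is.null(ct$side)) ct$side else NA,
                     x = ct$x, y = ct$y, p = ev$value[, 3], extrap_dist = 0)
    df[order(df$side, df$station), ]
  }))
  if (!is.null(scaling))
    out$Cp <- out$p / (0.5 * scaling$rho * scaling$U^2)
  rownames(out) <- NULL
  out
}

#' Desk-scale and reference training presets
#'
#' Bundled network/training configurations: `"paper"` is the reference
#' configuration (12 x 120 sigmoid network, 1500 epochs, minibatch 10000);
#' the desk presets are small enough to train in minutes on one CPU and are
#' used by the package's examples and validation suite.
#'
#' @param name preset name
#' @param init_seed,sampling_seed seeds applied to the preset
#' @return list with elements `network` and `training`
#' @export
pinn_preset <- function(name = c("desk-taylor-green", "desk-swimmer", "paper"),
                        init_seed = 1L, sampling_seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "desk-taylor-green" = list(
      network = network_config(4, 64, "tanh", init_seed = init_seed),
      training = training_config(epochs = 200, minibatch = 1024,
                                 learning_rate = 7e-3, lr_decay = 0.5,
                                 lr_decay_every = 50,
                                 sampling_seed = sampling_seed)),
    "desk-swimmer" = list(
      network = network_config(4, 48, "tanh", init_seed = init_seed),
      training = training_config(epochs = 60, minibatch = 1024,
                                 learning_rate = 1e-2, lr_decay = 0.5,
                                 lr_decay_every = 25,
                                 sampling_seed = sampling_seed)),
    "paper" = list(
      network = network_config(12, 120, "sigmoid", init_seed = init_seed),
      training = training_config(epochs = 1500, minibatch = 10000,
                                 sampling_seed = sampling_seed)))
}
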