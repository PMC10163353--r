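#' Exact surrogate surface pressure, all times
#'
#' Evaluates the potential-swimmer surrogate's Bernoulli pressure exactly on
#' the contour points of its kinematics, the ground truth for surface-error
#' metrics.
#'
#' @param params the [carangiform_params()] used to build the surrogate
#' @param kinematics the surrogate's [body_kinematics()]
#' @param U_inf,n_dipoles must match the [potential_swimmer_truth()] call
#' @return data frame with `time`, `station`, `side`, `x`, `y`, `p`,
#'   ordered by time, side, station
#' @export
swimmer_surface_truth <- function(params, kinematics, U_inf = 1,
                                  n_dipoles = 3) {
  dfs <- swimmer_surface_pressure(params, kinematics, U_inf, n_dipoles)
  out <- do.call(rbind, lapply(seq_along(kinematics$times), function(it)
    cbind(time = kinematics$times[it], dfs[[it]])))
  out[order(out$time, out$side, out$station), ]
}

# additive offset that moves `pred` onto the gauge of `truth`, computed by
# matching field means over the common valid nodes
gauge_offset <- function(pred, truth) {
  ok <- pred$mask & truth$mask & is.finite(pred$p) & is.finite(truth$p)
  mean(truth$p[ok]) - mean(pred$p[ok])
}

subset_times <- function(surface, times, tol = 1e-8) {
  keep <- vapply(surface$time, function(tt) any(abs(times - tt) <= tol), TRUE)
  surface[keep, ]
}

#' Resolution-sensitivity sweep
#'
#' Reproduces the resolution study design: the ground-truth velocity field
#' is coarsened to each requested spatial (and temporal) step, each method
#' reconstructs the pressure, and the relative global surface RMSE
#' ([relative_global_rmse()]) against the exact surrogate surface pressure
#' is recorded. The momentum residuals of the network are always evaluated
#' on the finest available grid regardless of the measurement resolution;
#' the integration baseline sees only the coarsened measurements.
#'
#' @param truth output of [potential_swimmer_truth()]
#' @param params the [carangiform_params()] used to build `truth`
#' @param methods subset of `c("pinn", "integration")`
#' @param spatial_steps grid spacings in body lengths; must be integer
#'   multiples of the truth spacing
#' @param temporal_step time step in periods; integer multiple of the truth
#'   step
#' @param seeds integer vector; the network is retrained per seed (the
#'   baseline is deterministic and ignores seeds beyond the first)
#' @param Re Reynolds number used in the residuals (the surrogate satisfies
#'   the equations at any Re)
#' @param preset desk-scale preset name for the network runs
#' @param exclude_x_gt station-exclusion threshold of the metric
#' @return data frame with `method`, `spatial_step`, `temporal_step`,
#'   `seed`, `rmse` (percent)
#' @export
run_resolution_sweep <- function(truth, params,
                                 methods = c("pinn", "integration"),
                                 spatial_steps = c(0.02, 0.06, 0.1),
                                 temporal_step = 0.02, seeds = 1L,
                                 Re = 5000, preset = "desk-swimmer",
                                 exclude_x_gt = 0.9) {
  methods <- match.arg(methods, several.ok = TRUE)
  hx <- truth$velocity$x[2] - truth$velocity$x[1]
  ht <- truth$velocity$t[2] - truth$velocity$t[1]
  kt <- int_stride(temporal_step / ht)
  surf_truth <- swimmer_surface_truth(params, truth$kinematics)
  rows <- list()
  for (step in spatial_steps) {
    ks <- int_stride(step / hx)
    ds <- downsample_series(truth$velocity, ks, kt)
    times <- ds$t
    st <- subset_times(surf_truth, times)
    hp <- head_pressure(surf_truth)
    if ("integration" %in% methods) {
      err <- tryCatch({
        grad <- pressure_gradient_field(ds, Re)
        prec <- integrate_multidirectional(grad)
        surf <- nearest_point_surface_pressure(prec, truth$kinematics, times)
        surf <- surf[order(surf$time, surf$side, surf$station), ]
        off <- gauge_offset(prec, truth_on_grid(truth$pressure, ds))
        surf$p <- surf$p + off
        relative_global_rmse(surf, st, hp, exclude_x_gt)
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <-
        data.frame(method = "integration", spatial_step = step,
                   temporal_step = temporal_step, seed = seeds[1], rmse = err)
    }
    if ("pinn" %in% methods) {
      for (sd in seeds) {
        ps <- pinn_preset(preset, init_seed = sd, sampling_seed = sd + 1000L)
        ps$training$enforce_continuity <- TRUE  # the surrogate is exactly 2D
        # equalize the optimizer-step budget across resolutions: an epoch is
        # one pass over the measured vectors, so coarser measurements would
        # otherwise get proportionally fewer updates
        fine_iters <- ceiling(sum(truth$velocity$mask) / ps$training$minibatch)
        ds_iters <- ceiling(sum(ds$mask) / ps$training$minibatch)
        frac <- ps$training$lr_decay_every / ps$training$epochs
        ps$training$epochs <- as.integer(ceiling(ps$training$epochs *
                                                   fine_iters / ds_iters))
        ps$training$lr_decay_every <- max(1L, as.integer(ps$training$epochs * frac))
        fit <- pinn(ds, kinematics = truth$kinematics,
                    bc = boundary_spec(body = FALSE), Re = Re,
                    network = ps$network, training = ps$training,
                    collocation = list(x = truth$velocity$x,
                                       y = truth$velocity$y, t = times))
        pf <- predict_field(fit, like = truth$velocity, times = times,
                            kinematics = truth$kinematics)
        off <- gauge_offset(pf$pressure, truth_on_grid(truth$pressure, pf$pressure)) +
          (attr(pf$pressure, "gauge_shift") %||% 0)
        surf <- surface_pressure(fit, truth$kinematics, times = times)
        surf <- surf[order(surf$time, surf$side, surf$station), ]
        surf$p <- surf$p + off
        rows[[length(rows) + 1]] <-
          data.frame(method = "pinn", spatial_step = step,
                     temporal_step = temporal_step, seed = sd,
                     rmse = relative_global_rmse(surf, st, hp, exclude_x_gt))
      }
    }
  }
  do.call(rbind, rows)
}

int_stride <- function(r) {
  k <- round(r)
  if (abs(r - k) > 1e-6 || k < 1)
    stop("requested step is not an integer multiple of the source resolution")
  as.integer(k)
}

# restrict a truth pressure series onto the grid/times of another series
truth_on_grid <- function(pres, like) {
  ix <- match_axis(pres$x, like$x); iy <- match_axis(pres$y, like$y)
  it <- match_axis(pres$t, like$t)
  pressure_series(pres$x[ix], pres$y[iy], pres$t[it],
                  pres$p[ix, iy, it, drop = FALSE], gauge = pres$gauge,
                  mask = pres$mask[ix, iy, it, drop = FALSE])
}

match_axis <- function(a, b, tol = 1e-8) {
  idx <- vapply(b, function(v) {
    i <- which.min(abs(a - v))
    if (abs(a[i] - v) > tol) stop("grids are not nested")
    i
  }, 0L)
  idx
}

#' Noise-sensitivity sweep
#'
#' Adds white measurement noise at each level (fraction of the reference
#' velocity) to the ground-truth velocities, reconstructs with each method,
#' and reports the surface error per seed.
#'
#' @inheritParams run_resolution_sweep
#' @param levels noise levels (fractions of the maximum velocity magnitude)
#' @param seeds one reconstruction per (level, seed); seeds drive both the
#'   noise draw and the network initialization
#' @return data frame with `method`, `level`, `seed`, `rmse`
#' @export
run_noise_sweep <- function(truth, params, methods = c("pinn", "integration"),
                            levels = c(0, 0.05, 0.1), seeds = 1L,
                            Re = 5000, preset = "desk-swimmer",
                            exclude_x_gt = 0.9) {
  methods <- match.arg(methods, several.ok = TRUE)
  surf_truth <- swimmer_surface_truth(params, truth$kinematics)
  hp <- head_pressure(surf_truth)
  times <- truth$velocity$t
  st <- subset_times(surf_truth, times)
  rows <- list()
  for (lev in levels) for (sd in seeds) {
    noisy <- add_noise(truth$velocity, lev, seed = sd)
    if ("integration" %in% methods) {
      err <- tryCatch({
        prec <- integrate_multidirectional(pressure_gradient_field(noisy, Re))
        surf <- nearest_point_surface_pressure(prec, truth$kinematics, times)
        surf <- surf[order(surf$time, surf$side, surf$station), ]
        surf$p <- surf$p + gauge_offset(prec, truth$pressure)
        relative_global_rmse(surf, st, hp, exclude_x_gt)
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <-
        data.frame(method = "integration", level = lev, seed = sd, rmse = err)
    }
    if ("pinn" %in% methods) {
      ps <- pinn_preset(preset, init_seed = sd, sampling_seed = sd + 1000L)
      ps$training$enforce_continuity <- TRUE
      fit <- pinn(noisy, kinematics = truth$kinematics,
                  bc = boundary_spec(body = FALSE), Re = Re,
                  network = ps$network, training = ps$training)
      pf <- predict_field(fit, like = truth$velocity,
                          kinematics = truth$kinematics)
      surf <- surface_pressure(fit, truth$kinematics, times = times)
      surf <- surf[order(surf$time, surf$side, surf$station), ]
      surf$p <- surf$p + gauge_offset(pf$pressure, truth$pressure) +
        (attr(pf$pressure, "gauge_shift") %||% 0)
      rows[[length(rows) + 1]] <-
        data.frame(method = "pinn", level = lev, seed = sd,
                   rmse = relative_global_rmse(surf, st, hp, exclude_x_gt))
    }
  }
  do.call(rbind, rows)
}
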