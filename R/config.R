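#' Build and validate a run configuration
#'
#' A run configuration fully determines a reproducible run of one of the
#' package's drivers: synthetic-data generation (`synth`), the network
#' reconstruction (`reconstruct`), a classical baseline (`baseline`) or an
#' evaluation (`evaluate`). Unknown keys are rejected by name; defaults are
#' injected for everything optional (network 12 x 120 sigmoid, minibatch
#' 10000, 1500 epochs, weights 100/0/100/1). A run is reproducible from its
#' archived resolved configuration and seeds alone.
#'
#' @param subcommand one of `"synth"`, `"reconstruct"`, `"baseline"`,
#'   `"evaluate"`
#' @param ... subcommand-specific fields, see Details
#' @details Recognized fields per subcommand:
#' * `synth`: `case` ("taylor-green" or "swimmer"), `nx`, `ny`, `times`,
#'   `Re`, `noise_level`, `seed`, `out`
#' * `reconstruct`: `dataset`, `kinematics` (dir or `NULL`), `Re`, `bc`
#'   (list of [boundary_spec()] fields), `network` (list of
#'   [network_config()] fields), `training` (list of [training_config()]
#'   fields), `weights` (list of [loss_weights()] fields), `out`
#' * `baseline`: `method` ("poisson" or "integration"), `dataset`, `Re`,
#'   `kinematics`, `out`
#' * `evaluate`: `pred`, `truth` (pressure-series dirs), `out`
#' @return an object of class `"run_config"`
#' @export
run_config <- function(subcommand = c("synth", "reconstruct", "baseline",
                                      "evaluate"), ...) {
  subcommand <- match.arg(subcommand)
  fields <- list(...)
  allowed <- switch(subcommand,
    synth = c("case", "nx", "ny", "times", "Re", "noise_level", "seed", "out"),
    reconstruct = c("dataset", "kinematics", "Re", "bc", "network",
                    "training", "weights", "collocation", "out"),
    baseline = c("method", "dataset", "Re", "kinematics", "out"),
    evaluate = c("pred", "truth", "out"))
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- switch(subcommand,
    synth = list(case = "taylor-green", nx = 32, ny = 32,
                 times = seq(0, 1, length.out = 10), Re = 100,
                 noise_level = 0, seed = 1L, out = NULL),
    reconstruct = list(dataset = NULL, kinematics = NULL, Re = NULL,
                       bc = list(), network = list(), training = list(),
                       weights = list(), collocation = NULL, out = NULL),
    baseline = list(method = "integration", dataset = NULL, Re = NULL,
                    kinematics = NULL, out = NULL),
    evaluate = list(pred = NULL, truth = NULL, out = NULL))
  cfg <- utils::modifyList(defaults, fields)
  cfg$subcommand <- subcommand
  # resolve nested specs so the archived config is fully explicit
  if (subcommand == "reconstruct") {
    if (is.null(cfg$dataset)) stop("missing dataset")
    cfg$bc <- do.call(boundary_spec,
                      utils::modifyList(list(body = !is.null(cfg$kinematics)),
                                        as.list(cfg$bc)))
    cfg$network <- do.call(network_config, as.list(cfg$network))
    cfg$training <- do.call(training_config, as.list(cfg$training))
    cfg$weights <- do.call(loss_weights, as.list(cfg$weights))
  }
  if (subcommand == "baseline") {
    if (is.null(cfg$dataset)) stop("missing dataset")
    cfg$method <- match.arg(cfg$method, c("integration", "poisson"))
  }
  if (subcommand == "synth")
    cfg$case <- match.arg(cfg$case, c("taylor-green", "swimmer"))
  structure(cfg, class = "run_config")
}

#' Load a run configuration from JSON (or YAML)
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`
#' @return a validated [run_config()]
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  sub <- raw$subcommand
  if (is.null(sub)) stop("config must name a subcommand")
  raw$subcommand <- NULL
  raw$package_version <- NULL  # provenance stamp added by write_run_config
  do.call(run_config, c(list(subcommand = sub), raw))
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  } else if (is.function(x)) return(NULL)
  x
}

#' Archive a resolved configuration as JSON
#'
#' @param cfg a [run_config()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_run_config <- function(cfg, path) {
  out <- strip_class(unclass(cfg))
  out$package_version <- as.character(utils::packageVersion("pivpressure"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Execute a run configuration
#'
#' Runs the configured driver, writes its outputs (field series in the
#' package's directory format, surface-pressure CSVs, per-epoch loss
#' history) plus the archived resolved configuration into the output
#' directory. A rerun from the archived configuration reproduces the
#' outputs bit-identically.
#'
#' @param cfg a [run_config()] (or a path to one)
#' @param dry_run validate and archive only, skip computation
#' @return list of produced artifact paths, invisibly
#' @export
run_case <- function(cfg, dry_run = FALSE) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$out)) stop("missing output directory 'out'")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  write_run_config(cfg, file.path(cfg$out, "config.json"))
  if (dry_run) return(invisible(list(config = file.path(cfg$out, "config.json"))))
  arts <- list(config = file.path(cfg$out, "config.json"))
  if (cfg$subcommand == "synth") {
    if (cfg$case == "taylor-green") {
      tg <- taylor_green_truth(cfg$nx, cfg$ny, cfg$times, cfg$Re)
      vel <- tg$velocity; pres <- tg$pressure; kin <- NULL
    } else {
      params <- carangiform_params()
      sw <- potential_swimmer_truth(params, times = cfg$times)
      vel <- sw$velocity; pres <- sw$pressure; kin <- sw$kinematics
    }
    if (cfg$noise_level > 0)
      vel <- add_noise(vel, cfg$noise_level, seed = cfg$seed)
    write_velocity_series(vel, file.path(cfg$out, "velocity"))
    write_pressure_series(pres, file.path(cfg$out, "pressure"))
    if (!is.null(kin))
      write_body_kinematics(kin, file.path(cfg$out, "kinematics"))
    arts$velocity <- file.path(cfg$out, "velocity")
  } else if (cfg$subcommand == "baseline") {
    vel <- read_velocity_series(cfg$dataset)
    Re <- cfg$Re %||% attr(vel, "scaling")$Re
    pres <- if (cfg$method == "poisson") solve_poisson(vel, Re)
            else integrate_multidirectional(pressure_gradient_field(vel, Re))
    write_pressure_series(pres, file.path(cfg$out, "pressure"))
    if (!is.null(cfg$kinematics)) {
      kin <- read_body_kinematics(cfg$kinematics)
      surf <- nearest_point_surface_pressure(pres, kin)
      write.csv(surf, file.path(cfg$out, "surface_pressure.csv"),
                row.names = FALSE)
    }
    arts$pressure <- file.path(cfg$out, "pressure")
  } else if (cfg$subcommand == "reconstruct") {
    vel <- read_velocity_series(cfg$dataset)
    kin <- if (!is.null(cfg$kinematics)) read_body_kinematics(cfg$kinematics)
    fit <- pinn(vel, kinematics = kin, bc = cfg$bc, Re = cfg$Re,
                network = cfg$network, training = cfg$training,
                weights = cfg$weights, collocation = cfg$collocation)
    write.csv(fit$history, file.path(cfg$out, "loss_history.csv"),
              row.names = FALSE)
    pf <- predict_field(fit, like = vel, kinematics = kin)
    write_velocity_series(pf$velocity, file.path(cfg$out, "velocity"))
    write_pressure_series(pf$pressure, file.path(cfg$out, "pressure"))
    if (!is.null(kin)) {
      surf <- surface_pressure(fit, kin)
      write.csv(surf, file.path(cfg$out, "surface_pressure.csv"),
                row.names = FALSE)
    }
    writeLines(sprintf("%.17g", fit$theta),
               file.path(cfg$out, "checkpoint_theta.txt"))
    arts$pressure <- file.path(cfg$out, "pressure")
  } else if (cfg$subcommand == "evaluate") {
    pred <- read_pressure_series(cfg$pred)
    truth <- read_pressure_series(cfg$truth)
    res <- list(field_rmse = field_rmse(pred, truth),
                field_rmse_relative = field_rmse(pred, truth, relative = TRUE))
    jsonlite::write_json(res, file.path(cfg$out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    arts$metrics <- file.path(cfg$out, "metrics.json")
  }
  invisible(arts)
}
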