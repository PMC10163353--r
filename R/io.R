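# On-disk format: a directory holding metadata.json (grid, times, units,
# gauge, optional scaling) plus one CSV per time step per component
# (u_0001.csv, v_0001.csv, p_0001.csv, mask_0001.csv, contour_0001.csv).
# CSVs are comma-separated with no header, rows = y, columns = x, written
# with 17 significant digits so that a text round-trip reproduces doubles
# exactly.

fmt_num <- function(m) {
  s <- sprintf("%.17g", m)
  dim(s) <- dim(m)
  s
}

write_mat_csv <- function(m, path) {
  write.table(fmt_num(m), path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

read_mat_csv <- function(path) {
  if (!file.exists(path)) stop("missing time step file: ", path)
  as.matrix(read.csv(path, header = FALSE))
}

scaling_to_list <- function(s) s[c("L", "T", "U", "rho", "nu", "Re")]

#' Write a velocity series to a directory
#'
#' One CSV per time step per component (rows = y, columns = x) plus a JSON
#' metadata descriptor holding the axes, units and optional scaling. Masked
#' nodes are written as NaN and recorded in `mask_*.csv`.
#'
#' @param series a [velocity_series()]
#' @param path output directory (created if needed)
#' @return `path`, invisibly
#' @export
write_velocity_series <- function(series, path) {
  stopifnot(inherits(series, "velocity_series"))
  if (length(series$t) == 0) stop("empty series")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(kind = "velocity", x = series$x, y = series$y, t = series$t,
               units = attr(series, "units"))
  sc <- attr(series, "scaling")
  if (!is.null(sc)) meta$scaling <- scaling_to_list(sc)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (it in seq_along(series$t)) {
    u <- t(series$u[, , it]); v <- t(series$v[, , it])
    m <- t(series$mask[, , it])
    u[!m] <- NaN; v[!m] <- NaN
    write_mat_csv(u, file.path(path, sprintf("u_%04d.csv", it)))
    write_mat_csv(v, file.path(path, sprintf("v_%04d.csv", it)))
    write_mat_csv(m + 0, file.path(path, sprintf("mask_%04d.csv", it)))
  }
  invisible(path)
}

#' Read a velocity series from a directory
#'
#' Validates the metadata (strictly increasing uniform axes), rejects NaN
#' velocities at valid (unmasked) nodes, and non-dimensionalizes on the fly
#' when the metadata declares dimensional units and carries a scaling set
#' (or one is supplied).
#'
#' @param path directory written by [write_velocity_series()]
#' @param scaling optional [scaling_set()] overriding the stored one
#' @return a [velocity_series()]
#' @export
read_velocity_series <- function(path, scaling = NULL) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  x <- meta$x; y <- meta$y; tt <- meta$t
  if (any(diff(tt) <= 0)) stop("times not increasing")
  dims <- c(length(x), length(y), length(tt))
  u <- array(NA_real_, dims); v <- array(NA_real_, dims)
  mask <- array(TRUE, dims)
  for (it in seq_along(tt)) {
    u[, , it] <- t(read_mat_csv(file.path(path, sprintf("u_%04d.csv", it))))
    v[, , it] <- t(read_mat_csv(file.path(path, sprintf("v_%04d.csv", it))))
    mf <- file.path(path, sprintf("mask_%04d.csv", it))
    if (file.exists(mf)) mask[, , it] <- t(read_mat_csv(mf)) != 0
  }
  if (any(!is.finite(u[mask])) || any(!is.finite(v[mask])))
    stop("NaN velocity in valid (unmasked) region")
  u[!mask] <- NA; v[!mask] <- NA
  ser <- velocity_series(x, y, tt, u, v, mask,
                         units = meta$units %||% "nondimensional")
  if (!is.null(meta$scaling) && is.null(scaling))
    scaling <- do.call(scaling_set, meta$scaling)
  if (!is.null(scaling)) {
    attr(ser, "scaling") <- scaling
    if (is_dimensional(ser)) ser <- nondimensionalize(ser, scaling)
  }
  ser
}

#' Write / read a pressure series
#'
#' Same directory format as the velocity series, with `p_*.csv` files and
#' the gauge recorded in the metadata.
#'
#' @param series a [pressure_series()]
#' @param path directory
#' @return `path` (write) or a [pressure_series()] (read)
#' @export
write_pressure_series <- function(series, path) {
  stopifnot(inherits(series, "pressure_series"))
  if (length(series$t) == 0) stop("empty series")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(kind = "pressure", x = series$x, y = series$y, t = series$t,
               units = attr(series, "units"), gauge = series$gauge)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (it in seq_along(series$t)) {
    p <- t(series$p[, , it]); m <- t(series$mask[, , it])
    p[!m] <- NaN
    write_mat_csv(p, file.path(path, sprintf("p_%04d.csv", it)))
    write_mat_csv(m + 0, file.path(path, sprintf("mask_%04d.csv", it)))
  }
  invisible(path)
}

#' @rdname write_pressure_series
#' @export
read_pressure_series <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  tt <- meta$t
  if (any(diff(tt) <= 0)) stop("times not increasing")
  dims <- c(length(meta$x), length(meta$y), length(tt))
  p <- array(NA_real_, dims); mask <- array(TRUE, dims)
  for (it in seq_along(tt)) {
    p[, , it] <- t(read_mat_csv(file.path(path, sprintf("p_%04d.csv", it))))
    mf <- file.path(path, sprintf("mask_%04d.csv", it))
    if (file.exists(mf)) mask[, , it] <- t(read_mat_csv(mf)) != 0
  }
  pressure_series(meta$x, meta$y, tt, p, gauge = meta$gauge %||% "zero_mean",
                  mask = mask, units = meta$units %||% "nondimensional")
}

#' Write / read body kinematics
#'
#' One `contour_*.csv` per time step with columns `x`, `y`, `u`, `v` (and
#' `station`, `side` when present); normals and normal velocities are
#' recomputed on read.
#'
#' @param kin a [body_kinematics()]
#' @param path directory
#' @return `path` (write) or a [body_kinematics()] (read)
#' @export
write_body_kinematics <- function(kin, path) {
  stopifnot(inherits(kin, "body_kinematics"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(kind = "kinematics", t = kin$times),
                       file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (it in seq_along(kin$times)) {
    ct <- kin$contours[[it]]
    cols <- intersect(c("x", "y", "u", "v", "station", "side"), names(ct))
    df <- ct[cols]
    for (nm in setdiff(cols, "side")) df[[nm]] <- sprintf("%.17g", df[[nm]])
    write.csv(df, file.path(path, sprintf("contour_%04d.csv", it)),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_body_kinematics
#' @export
read_body_kinematics <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  contours <- lapply(seq_along(meta$t), function(it) {
    f <- file.path(path, sprintf("contour_%04d.csv", it))
    if (!file.exists(f)) stop("missing time step file: ", f)
    read.csv(f)
  })
  body_kinematics(meta$t, contours)
}
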