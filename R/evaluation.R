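#' Relative global surface-pressure RMSE
#'
#' The accuracy metric for surface-pressure reconstruction: the root of the
#' mean (over retained surface points and all time steps, a single global
#' mean) squared difference between predicted and true non-dimensional
#' surface pressure, normalized by the magnitude of the head pressure and
#' reported as a percentage. Points with axial station `x > exclude_x_gt`
#' (in body lengths) are excluded before any aggregation, since the flow
#' near the tail is strongly three-dimensional and its in-plane error is
#' not informative. The head pressure is the stagnation-region surface
#' pressure at the nose; see [head_pressure()].
#'
#' @param pred,truth surface-pressure data frames with columns `station`
#'   and `p` sampled at matching points and times (e.g. from
#'   [surface_pressure()] / [nearest_point_surface_pressure()] and the
#'   truth generator)
#' @param head_pressure normalizer (nonzero); typically
#'   `head_pressure(truth)`
#' @param exclude_x_gt exclusion threshold in body lengths (default 0.9)
#' @return the relative global RMSE in percent
#' @export
relative_global_rmse <- function(pred, truth, head_pressure,
                                 exclude_x_gt = 0.9) {
  if (nrow(pred) != nrow(truth))
    stop("prediction and truth must be sampled at matching surface points")
  if (!is.finite(head_pressure) || abs(head_pressure) < 1e-12)
    stop("head pressure is (near) zero; metric undefined")
  keep <- truth$station <= exclude_x_gt
  d <- pred$p[keep] - truth$p[keep]
  d <- d[is.finite(d)]
  if (length(d) == 0) stop("no retained surface points")
  100 * sqrt(mean(d^2)) / abs(head_pressure)
}

#' Head (stagnation) pressure of a surface-pressure series
#'
#' Operationalized as the true surface pressure at the nose station
#' (`station == min(station)`), averaged over time.
#'
#' @param surface a surface-pressure data frame with `station`, `p` (and
#'   optionally `time`)
#' @return scalar head pressure
#' @export
head_pressure <- function(surface) {
  s0 <- min(surface$station, na.rm = TRUE)
  mean(surface$p[surface$station == s0], na.rm = TRUE)
}

#' Pressure coefficient
#'
#' `Cp = p / (rho U^2 / 2)` under the declared gauge of the series.
#'
#' @param series a [pressure_series()] (or numeric vector of pressures)
#' @param scaling a [scaling_set()]
#' @return series (or vector) of `Cp` values
#' @export
pressure_coefficient <- function(series, scaling) {
  stopifnot(inherits(scaling, "scaling_set"))
  if (scaling$U == 0) stop("characteristic velocity is zero")
  q <- 0.5 * scaling$rho * scaling$U^2
  if (inherits(series, "pressure_series")) {
    series$p <- series$p / q
    series
  } else series / q
}

#' Left-right surface pressure difference
#'
#' `delta Cp(x/L) = Cp_left - Cp_right`, the side-to-side pressure
#' difference a lateral line is thought to sense, sampled nose-to-tail. If
#' the two sides are sampled at different stations the right side is
#' linearly interpolated onto the left side's stations.
#'
#' @param left,right data frames with `station` and `p` (or `Cp`)
#' @param value column to difference (default `"p"`)
#' @return data frame with `station` and `delta`
#' @export
delta_cp <- function(left, right, value = "p") {
  l <- left[order(left$station), ]
  r <- right[order(right$station), ]
  if (max(min(r$station), min(l$station)) >
      min(max(r$station), max(l$station)))
    stop("non-overlapping station ranges")
  keep <- l$station >= min(r$station) & l$station <= max(r$station)
  l <- l[keep, ]
  rp <- approx(r$station, r[[value]], xout = l$station, ties = mean)$y
  data.frame(station = l$station, delta = l[[value]] - rp)
}

# align two pressure series defined on the same grid for gauge-free
# comparison: subtract each one's mean over the common valid nodes
align_gauge <- function(p1, p2) {
  ok <- p1$mask & p2$mask & is.finite(p1$p) & is.finite(p2$p)
  list(p1 = p1$p - mean(p1$p[ok]), p2 = p2$p - mean(p2$p[ok]), ok = ok)
}

#' Gauge-removed field RMSE between two pressure series
#'
#' Root-mean-square difference over the common valid nodes after removing
#' each series' mean (pressure is only defined up to a constant unless a
#' pressure boundary condition pinned it).
#'
#' @param pred,truth [pressure_series()] on the same grid
#' @param relative divide by the range of the (gauge-removed) truth
#' @return scalar RMSE (fraction of the truth range if `relative`)
#' @export
field_rmse <- function(pred, truth, relative = FALSE) {
  al <- align_gauge(pred, truth)
  rmse <- sqrt(mean((al$p1[al$ok] - al$p2[al$ok])^2))
  if (relative) rmse / diff(range(al$p2[al$ok])) else rmse
}
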