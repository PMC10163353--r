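#' Degradation of a velocity series: resolution coarsening
#'
#' Pure subsampling (no smoothing) of a velocity series by integer strides
#' in space and time, emulating PIV acquisitions with a larger field of view
#' or a slower camera. The validity mask is carried along. Composing two
#' downsampling steps equals a single combined one.
#'
#' @param series a [velocity_series()]
#' @param stride_space,stride_time positive integer strides; a stride of `k`
#'   keeps every `k`-th node starting from the first
#' @return the subsampled [velocity_series()]
#' @export
downsample_series <- function(series, stride_space = 1L, stride_time = 1L) {
  stopifnot(inherits(series, "velocity_series"))
  ks <- stride_space; kt <- stride_time
  if (ks != round(ks) || kt != round(kt) || ks < 1 || kt < 1)
    stop("strides must be positive integers")
  ix <- seq(1, length(series$x), by = ks)
  iy <- seq(1, length(series$y), by = ks)
  it <- seq(1, length(series$t), by = kt)
  velocity_series(series$x[ix], series$y[iy], series$t[it],
                  series$u[ix, iy, it, drop = FALSE],
                  series$v[ix, iy, it, drop = FALSE],
                  series$mask[ix, iy, it, drop = FALSE],
                  units = attr(series, "units"))
}

#' Degradation of a velocity series: additive white measurement noise
#'
#' Adds independent zero-mean Gaussian perturbations to `u` and `v` at valid
#' nodes only, with standard deviation `level * U_ref`. The reference
#' velocity defaults to the maximum velocity magnitude over the clean
#' series. Fully reproducible under `seed`.
#'
#' @param series a [velocity_series()]
#' @param level noise level as a fraction of `U_ref` (>= 0)
#' @param seed integer seed (required for `level > 0`)
#' @param U_ref reference velocity; default `max(sqrt(u^2 + v^2))` over
#'   valid nodes
#' @return the noisy [velocity_series()]
#' @export
add_noise <- function(series, level, seed = NULL, U_ref = NULL) {
  stopifnot(inherits(series, "velocity_series"))
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(series)
  if (is.null(seed)) stop("a seed is required for noise injection")
  if (is.null(U_ref)) {
    ok <- series$mask
    U_ref <- max(sqrt(series$u[ok]^2 + series$v[ok]^2))
  }
  n <- sum(series$mask)
  noise <- with_local_seed(seed, matrix(rnorm(2 * n, 0, level * U_ref), ncol = 2))
  series$u[series$mask] <- series$u[series$mask] + noise[, 1]
  series$v[series$mask] <- series$v[series$mask] + noise[, 2]
  series
}

# Evaluate thunk under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
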