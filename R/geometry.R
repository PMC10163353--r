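# Planar polygon utilities used for the body contour: signed area,
# outward vertex normals, point-in-polygon with an on-boundary-counts-as-
# inside convention (vectors measured on the fluid-body interface are
# treated like interior vectors and removed).

polygon_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Point-in-polygon test
#'
#' Even-odd ray-casting test of points against a closed polygon. Points
#' lying on the polygon boundary (within `tol`) are counted as inside,
#' matching the masking convention for grid nodes on the fluid-body
#' interface.
#'
#' @param px,py point coordinates
#' @param vx,vy polygon vertex coordinates (closed implicitly; the last
#'   vertex may but need not repeat the first)
#' @param tol distance within which a point counts as on the boundary
#' @return logical vector, `TRUE` for inside (or on-boundary) points
#' @export
point_in_polygon <- function(px, py, vx, vy, tol = 1e-12) {
  n <- length(vx)
  if (n >= 2 && vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n]; n <- n - 1 }
  if (n < 3) stop("polygon needs at least 3 distinct vertices")
  inside <- rep(FALSE, length(px))
  onbnd <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # even-odd crossing of the horizontal ray towards +x
    cross <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
    # distance to the segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    s <- if (L2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2)) else 0
    d2 <- (px - (x1 + s * dx))^2 + (py - (y1 + s * dy))^2
    onbnd <- onbnd | (d2 <= tol^2)
    j <- i
  }
  inside | onbnd
}

# Outward unit normals at polygon vertices from adjacent edge tangents.
# Orientation detected from the signed area.
polygon_normals <- function(x, y) {
  n <- length(x)
  closed <- n >= 2 && x[1] == x[n] && y[1] == y[n]
  if (closed) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  tx <- x[ip] - x[im]; ty <- y[ip] - y[im]
  len <- sqrt(tx^2 + ty^2)
  if (any(len == 0)) stop("degenerate contour: repeated adjacent vertices")
  tx <- tx / len; ty <- ty / len
  # for counter-clockwise traversal the interior lies left of travel, so the
  # outward normal is the right-hand normal of the tangent; flip if clockwise
  nx <- ty; ny <- -tx
  if (polygon_signed_area(x, y) < 0) { nx <- -nx; ny <- -ny }
  out <- cbind(nx = nx, ny = ny)
  if (closed) out <- rbind(out, out[1, , drop = FALSE])
  out
}
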