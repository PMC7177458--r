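## Planar geometry primitives shared by the network and exposure code.
## All coordinates are metres in a projected CRS; no spherical maths anywhere.

#' Euclidean (straight-line) distance between two planar points
#'
#' Distances are planar L2 norms; inputs must be projected coordinates in
#' metres. Vectorised over coordinates.
#'
#' @param ax,ay,bx,by coordinates of the two points (metres).
#' @return distance in metres.
#' @export
#' @examples
#' euclidean_distance(0, 0, 300, 400) # 500
euclidean_distance <- function(ax, ay, bx, by) {
  stopifnot(all(is.finite(c(ax, ay, bx, by))))
  sqrt((ax - bx)^2 + (ay - by)^2)
}

## Distance from point(s) (px, py) to the segment a-b, plus the parameter
## t in [0, 1] of the closest point along the segment. Vectorised over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 < .Machine$double.eps) {
    t <- rep(0, length(px))
  } else {
    t <- ((px - ax) * dx + (py - ay) * dy) / len2
    t <- pmin(1, pmax(0, t))
  }
  qx <- ax + t * dx
  qy <- ay + t * dy
  list(dist = sqrt((px - qx)^2 + (py - qy)^2), t = t, x = qx, y = qy)
}

## Ray-casting point-in-polygon. poly is a matrix with columns x, y
## (ring need not be closed). Boundary points count as inside.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xs2 <- xs[c(2:n, 1)]; ys2 <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs2[i]; y2 <- ys2[i]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- xint > px[crosses]
      inside[crosses] <- xor(inside[crosses], flip)
    }
  }
  inside
}

## Shoelace area of a polygon ring (matrix with columns x, y), in m^2.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
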