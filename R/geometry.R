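# Small computational-geometry kernel shared by the annotation, distance,
# profile and silhouette code. All coordinates are (x, y) in micrometers,
# origin at the top-left pixel corner, pixel centers at half-integer
# multiples of the pixel size. Matrices of points are n x 2 (x, y).

#' Minimum Euclidean distance from points to a polyline
#'
#' Computes, for each query point, the minimum distance to an open polyline
#' by projecting onto every segment and clamping the projection parameter to
#' the segment.
#'
#' @param points numeric matrix (n x 2) of query points, micrometers.
#' @param polyline numeric matrix (m x 2, m >= 2) of ordered vertices.
#' @return numeric vector of length n of distances (micrometers).
#' @export
point_polyline_distance <- function(points, polyline) {
  points <- as_points(points)
  polyline <- as_points(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 vertices")
  ax <- polyline[-nrow(polyline), 1L]; ay <- polyline[-nrow(polyline), 2L]
  bx <- polyline[-1L, 1L];             by <- polyline[-1L, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  d2 <- vapply(seq_len(nrow(points)), function(i) {
    px <- points[i, 1L]; py <- points[i, 2L]
    t <- ((px - ax) * dx + (py - ay) * dy) / pmax(len2, .Machine$double.xmin)
    t <- pmin(pmax(t, 0), 1)
    t[len2 == 0] <- 0  # degenerate zero-length segment
    qx <- ax + t * dx; qy <- ay + t * dy
    min((px - qx)^2 + (py - qy)^2)
  }, numeric(1L))
  sqrt(d2)
}

as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L, byrow = FALSE)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("points must be an n x 2 matrix of (x, y)")
  p
}

polyline_length <- function(poly) {
  poly <- as_points(poly)
  sum(sqrt(rowSums(diff(poly)^2)))
}

# Cumulative arc length at each vertex, starting at 0.
polyline_arclength <- function(poly) {
  poly <- as_points(poly)
  c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
}

# Resample a polyline at (approximately) fixed arc-length steps; endpoints
# are always included. Returns list(points, arclength).
resample_polyline <- function(poly, step_um) {
  poly <- as_points(poly)
  s <- polyline_arclength(poly)
  total <- s[length(s)]
  if (total <= 0) stop("polyline has zero length")
  n <- max(2L, ceiling(total / step_um) + 1L)
  grid <- seq(0, total, length.out = n)
  x <- stats::approx(s, poly[, 1L], xout = grid, ties = "ordered")$y
  y <- stats::approx(s, poly[, 2L], xout = grid, ties = "ordered")$y
  list(points = cbind(x, y), arclength = grid)
}

# Signed area of a closed polygon (shoelace); positive if counterclockwise
# in a y-up frame. The first vertex need not be repeated.
polygon_area <- function(poly) {
  poly <- close_polygon(as_points(poly))
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  0.5 * sum(x[-n] * y[-1L] - x[-1L] * y[-n])
}

polygon_perimeter <- function(poly) {
  polyline_length(close_polygon(as_points(poly)))
}

close_polygon <- function(poly) {
  if (!isTRUE(all.equal(poly[1L, ], poly[nrow(poly), ], check.attributes = FALSE)))
    poly <- rbind(poly, poly[1L, ])
  poly
}

# Proper-crossing test between segments p1-p2 and p3-p4 (shared endpoints
# between consecutive polyline segments do not count).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# TRUE if an open polyline intersects itself (non-adjacent segments cross).
polyline_self_intersects <- function(poly) {
  poly <- as_points(poly)
  ns <- nrow(poly) - 1L
  if (ns < 3L) return(FALSE)
  for (i in seq_len(ns - 2L)) {
    for (j in (i + 2L):ns) {
      if (segments_cross(poly[i, ], poly[i + 1L, ], poly[j, ], poly[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(points, poly) {
  points <- as_points(points); poly <- as_points(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(points))
  j <- n
  px <- points[, 1L]; py <- points[, 2L]
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Rasterize a simple polygon onto a pixel grid: TRUE where the pixel center
# falls inside. `dims` is c(ny, nx) (rows = y), pixel centers at
# ((col - 0.5) * px, (row - 0.5) * px).
rasterize_polygon <- function(poly, dims, pixel_size_um) {
  ny <- dims[1L]; nx <- dims[2L]
  cx <- (seq_len(nx) - 0.5) * pixel_size_um
  cy <- (seq_len(ny) - 0.5) * pixel_size_um
  pts <- cbind(rep(cx, each = ny), rep(cy, times = nx))
  matrix(points_in_polygon(pts, poly), nrow = ny, ncol = nx)
}

# Pixel-center coordinates (um) for a mask's TRUE pixels, n x 2.
mask_pixel_centers <- function(mask, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = (idx[, 2L] - 0.5) * pixel_size_um,
        y = (idx[, 1L] - 0.5) * pixel_size_um)
}
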