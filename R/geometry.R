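#' Planar polygon utilities
#'
#' Small set of exact planar-geometry helpers used throughout the package.
#' Polygons are plain two-column matrices of vertices (columns `x`, `y`, in
#' meters of a projected CRS), given as an open ring (the first vertex is not
#' repeated at the end); a closed ring is accepted and silently unclosed.
#'
#' @name polygon-utils
#' @keywords internal
NULL

# normalise a polygon argument to an open-ring 2-column matrix
as_ring <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L) stop("polygon must be a two-column (x, y) matrix")
  storage.mode(poly) <- "double"
  n <- nrow(poly)
  if (n >= 2L && all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

#' Validate a planar polygon
#'
#' Checks that a polygon is a simple (non-self-intersecting) ring with
#' positive area and finite coordinates. Used on home building footprints and
#' land-cover polygons before any point-in-polygon work.
#'
#' @param poly two-column matrix of vertices (open or closed ring).
#' @return the polygon as an open-ring matrix, invisibly; errors otherwise.
#' @export
validate_polygon <- function(poly) {
  poly <- as_ring(poly)
  if (nrow(poly) < 3L) stop("polygon must have at least 3 vertices")
  if (!all(is.finite(poly))) stop("polygon vertices must be finite")
  if (polygon_area(poly) <= 0) stop("polygon must have positive area")
  n <- nrow(poly)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # skip edges sharing a vertex
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(
        poly[idx[i], ], poly[idx[i + 1L], ],
        poly[idx[j], ], poly[idx[j + 1L], ]
      )) {
        stop("polygon is self-intersecting")
      }
    }
  }
  invisible(poly)
}

# proper intersection of open segments (shared endpoints do not count)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Polygon area (shoelace formula)
#'
#' @param poly two-column vertex matrix.
#' @return absolute area in squared coordinate units (m^2).
#' @export
polygon_area <- function(poly) {
  poly <- as_ring(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Polygon centroid
#'
#' Area-weighted centroid of a simple polygon.
#'
#' @param poly two-column vertex matrix.
#' @return numeric length-2 vector `(x, y)`.
#' @export
polygon_centroid <- function(poly) {
  poly <- as_ring(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Vectorised even-odd ray-casting test. Points lying exactly on a polygon
#' edge (within `eps` meters) count as inside: a cluster centroid sitting on a
#' building wall is treated as indoor.
#'
#' @param px,py numeric vectors of point coordinates (meters).
#' @param poly two-column vertex matrix.
#' @param eps boundary tolerance in meters.
#' @return logical vector, one element per point.
#' @export
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  poly <- as_ring(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    dx <- xj - xi; dy <- yj - yi
    l2 <- dx * dx + dy * dy
    tt <- if (l2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / l2)) else 0
    ex <- xi + tt * dx - px
    ey <- yi + tt * dy - py
    on_edge <- on_edge | (ex * ex + ey * ey <= eps * eps)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- inside != crosses
    j <- k
  }
  inside | on_edge
}

#' Axis-aligned square polygon
#'
#' Convenience constructor for building footprints in the synthetic
#' generator and in tests.
#'
#' @param cx,cy center coordinates (m).
#' @param side side length (m).
#' @return 4x2 vertex matrix (counter-clockwise, open ring).
#' @export
square_polygon <- function(cx, cy, side) {
  h <- side / 2
  cbind(
    x = c(cx - h, cx + h, cx + h, cx - h),
    y = c(cy - h, cy - h, cy + h, cy + h)
  )
}
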