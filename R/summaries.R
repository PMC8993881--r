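#' Fold range of utilization intensity within a contour
#'
#' Ratio of the highest to the lowest positive cell intensity among the
#' cells of the population surface's `level` volume contour (computed on the
#' normalized surface, so the contour is scale-free; the ratio itself is
#' scale-free too). A uniform surface returns 1.
#'
#' @param cs a `catscape`.
#' @param level contour level in `(0, 1]` (default 0.99).
#' @return max/min intensity ratio (>= 1).
#' @export
intensity_fold_range <- function(cs, level = 0.99) {
  ud <- normalize_catscape(cs)
  mask <- volume_contour(ud, level)$mask
  v <- cs$raster$values[mask]
  v <- v[v > 0]
  if (!length(v)) stop("contour contains no positive cells")
  if (max(v) == min(v)) return(1)
  max(v) / min(v)
}

#' Near-home intensity ratio
#'
#' Compares population utilization intensity close to cat homes against the
#' surrounding ring: the mean cell intensity over cells whose center lies
#' within `r1` of any home, divided by the mean cell intensity over cells
#' whose center lies in the `(r1, r2]` annulus of the nearest home (and not
#' within `r1` of any). Means per cell (not zone totals) make the two zones
#' comparable despite different areas.
#'
#' @param cs a `catscape`.
#' @param homes home points: an `n x 2` matrix, or a list of study-cat
#'   entries with a `home_point` field.
#' @param r1 inner radius (m), default 50.
#' @param r2 outer radius (m), default 100.
#' @return ratio of mean intensities (near / ring).
#' @export
near_home_intensity_ratio <- function(cs, homes, r1 = 50, r2 = 100) {
  stopifnot(inherits(cs, "catscape"), r2 > r1, r1 > 0)
  pts <- homes_to_points(homes)
  cx <- cell_centers_x(cs$grid)
  cy <- cell_centers_y(cs$grid)
  # distance from every cell center to the nearest home
  d2min <- matrix(Inf, cs$grid$n_rows, cs$grid$n_cols)
  for (k in seq_len(nrow(pts))) {
    dx2 <- (cx - pts[k, 1])^2
    dy2 <- (cy - pts[k, 2])^2
    d2min <- pmin(d2min, outer(dy2, dx2, `+`))
  }
  near <- d2min <= r1^2
  ring <- d2min > r1^2 & d2min <= r2^2
  if (!any(near)) stop("no cells within r1 of a home")
  if (!any(ring)) stop("empty annulus between r1 and r2")
  mean(cs$raster$values[near]) / mean(cs$raster$values[ring])
}

homes_to_points <- function(homes) {
  if (is.matrix(homes)) return(homes)
  if (is.numeric(homes) && length(homes) == 2) return(matrix(homes, 1))
  pts <- t(vapply(homes, function(h) {
    p <- if (is.list(h)) h$home_point else h
    as.numeric(p[1:2])
  }, numeric(2)))
  if (!nrow(pts)) stop("need at least one home")
  pts
}

#' Distance-to-home summary for one cat
#'
#' Mean and maximum Euclidean distance of outdoor fixes from the home point,
#' plus the fraction of fixes within `radius` -- a fix-count proxy for time,
#' since fixes arrive at a near-uniform rate.
#'
#' @param track outdoor-only `cat_track`.
#' @param home_point numeric `(x, y)` of the residence.
#' @param radius near-home radius (m), default 50.
#' @return one-row data frame: `cat_id`, `n_fixes`, `mean_dist_m`,
#'   `max_dist_m`, `frac_within`.
#' @export
distance_stats <- function(track, home_point, radius = 50) {
  if (!nrow(track$fixes)) stop("track has no fixes")
  d <- sqrt((track$fixes$x - home_point[1])^2 +
            (track$fixes$y - home_point[2])^2)
  data.frame(cat_id = track$cat_id, n_fixes = length(d),
             mean_dist_m = mean(d), max_dist_m = max(d),
             frac_within = mean(d <= radius))
}

#' Land-cover container
#'
#' A named list of land-cover classes, each a list of polygons (two-column
#' vertex matrices). `urban_classes` names the classes counted as "urban and
#' other developed areas"; everything not covered by them is "other".
#'
#' @param classes named list: class name -> list of polygons.
#' @param urban_classes character vector of developed-class names.
#' @return object of class `landcover`.
#' @export
landcover <- function(classes, urban_classes = intersect(c("urban", "developed"),
                                                         names(classes))) {
  stopifnot(is.list(classes), length(names(classes)) == length(classes))
  for (cls in classes) for (p in cls) validate_polygon(p)
  structure(list(classes = classes, urban_classes = urban_classes),
            class = "landcover")
}

# logical matrix: cell center inside any urban/developed polygon
urban_mask <- function(grid, lc) {
  stopifnot(inherits(lc, "landcover"))
  cx <- cell_centers_x(grid)
  cy <- cell_centers_y(grid)
  px <- rep(cx, each = grid$n_rows)
  py <- rep(cy, times = grid$n_cols)
  inside <- logical(length(px))
  for (nm in lc$urban_classes) {
    for (poly in lc$classes[[nm]]) {
      inside <- inside | point_in_polygon(px, py, poly)
    }
  }
  matrix(inside, grid$n_rows, grid$n_cols)
}

#' Partition a population surface by land cover
#'
#' Measures how much of the population surface extends beyond urban and
#' other developed areas: the fraction of the `level`-contour *area* whose
#' cell centers fall outside the developed classes, and the fraction of the
#' total surface *intensity* carried by those outside cells. Cell membership
#' is by cell-center point-in-polygon (a +-1-cell-edge approximation).
#'
#' @param cs a `catscape`.
#' @param lc a [landcover()].
#' @param level contour level used to delimit the surface (default 0.99).
#' @return list `fraction_area_outside`, `fraction_intensity_outside`,
#'   `contour_area_ha`.
#' @export
landcover_partition <- function(cs, lc, level = 0.99) {
  ud <- normalize_catscape(cs)
  mask <- volume_contour(ud, level)$mask
  urb <- urban_mask(cs$grid, lc)
  outside <- mask & !urb
  v <- cs$raster$values
  list(
    fraction_area_outside = sum(outside) / sum(mask),
    fraction_intensity_outside = sum(v[outside]) / sum(v),
    contour_area_ha = sum(mask) * cs$grid$cell_size^2 / 1e4
  )
}
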