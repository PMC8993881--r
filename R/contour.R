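#' Volume contour (isopleth) of a utilization distribution
#'
#' Finds the smallest set of cells containing at least `level` of the UD
#' mass: cells are sorted by value in decreasing order and accumulated until
#' the cumulative mass reaches `level`; all cells tied with the last included
#' value are included too. The contour region is the union of the selected
#' cell squares; its polygons are returned as cell-aligned rectangles (one
#' per maximal horizontal run of selected cells).
#'
#' @param ud a [ud_raster()] whose values sum to 1 (within 1e-6).
#' @param level mass level in `(0, 1]` (0.95 for the conventional home
#'   range, 0.5 for the core area).
#' @return object of class `volume_contour`: `level`, `mask` (logical
#'   matrix of selected cells), `polygons` (list of 4x2 vertex matrices),
#'   `area_ha`, `grid`.
#' @export
volume_contour <- function(ud, level) {
  stopifnot(inherits(ud, "ud_raster"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1)
    stop("level must be a single value in (0, 1]")
  total <- sum(ud$values)
  if (abs(total - 1) > 1e-6)
    stop("UD values must sum to 1; got ", format(total))
  v <- as.vector(ud$values)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  k <- which(cum >= level * total - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  threshold <- v[ord[k]]
  mask <- ud$values >= threshold & ud$values > 0
  structure(list(level = level, mask = mask,
                 polygons = mask_polygons(mask, ud$grid),
                 area_ha = sum(mask) * ud$grid$cell_size^2 / 1e4,
                 grid = ud$grid),
            class = "volume_contour")
}

#' @export
print.volume_contour <- function(x, ...) {
  cat(sprintf("volume_contour %.0f%%: %d cells, %.3f ha\n",
              x$level * 100, sum(x$mask), x$area_ha))
  invisible(x)
}

# cell-aligned rectangles: one per maximal horizontal run of TRUE cells
mask_polygons <- function(mask, grid) {
  polys <- list()
  cs <- grid$cell_size
  for (i in seq_len(nrow(mask))) {
    row <- mask[i, ]
    if (!any(row)) next
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    y1 <- grid$y_min + (grid$n_rows - i + 1) * cs
    y0 <- y1 - cs
    for (k in which(r$values)) {
      x0 <- grid$x_min + (starts[k] - 1L) * cs
      x1 <- grid$x_min + ends[k] * cs
      polys[[length(polys) + 1L]] <-
        cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
    }
  }
  polys
}

#' Home-range summary at several contour levels
#'
#' Convenience wrapper computing [volume_contour()] at each requested level
#' (defaults 50/95/99%: core area, conventional home range, full range).
#' Areas are non-decreasing in level by construction.
#'
#' @param ud a [ud_raster()].
#' @param levels numeric vector of mass levels in `(0, 1]`.
#' @return list with `contours` (named list of `volume_contour`) and
#'   `areas` (data frame `level`, `area_ha`).
#' @export
home_range_summary <- function(ud, levels = c(0.5, 0.95, 0.99)) {
  levels <- sort(unique(levels))
  contours <- lapply(levels, function(l) volume_contour(ud, l))
  names(contours) <- sprintf("%g", levels)
  list(contours = contours,
       areas = data.frame(
         level = levels,
         area_ha = vapply(contours, function(cc) cc$area_ha, numeric(1))))
}
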