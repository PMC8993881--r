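#' Raster grid definition
#'
#' A `grid_spec` describes a regular planar grid in a projected CRS:
#' `x_min`/`y_min` are the lower-left corner of the lower-left cell,
#' `cell_size` the square cell side in meters. Raster values are stored as an
#' `n_rows x n_cols` matrix with row 1 the northernmost row and column 1 the
#' westernmost column; cell `(i, j)` covers the half-open square
#' `[x_min + (j-1) c, x_min + j c) x (y_min + (n_rows - i) c, y_min + (n_rows - i + 1) c]`.
#'
#' @param x_min,y_min lower-left corner of the grid (m).
#' @param cell_size cell side (m), positive.
#' @param n_cols,n_rows positive integer grid dimensions.
#' @param crs_tag free-form identifier of the projected CRS.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(x_min, y_min, cell_size, n_cols, n_rows, crs_tag = "local") {
  stopifnot(is.finite(x_min), is.finite(y_min), cell_size > 0,
            n_cols >= 1, n_rows >= 1)
  structure(
    list(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         cell_size = as.numeric(cell_size),
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         crs_tag = crs_tag),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows, cell %g m, origin (%g, %g), crs %s\n",
              x$n_cols, x$n_rows, x$cell_size, x$x_min, x$y_min, x$crs_tag))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a `grid_spec`.
#' @return `cell_centers_x`: x of each column (west to east);
#'   `cell_centers_y`: y of each row (north to south, matching matrix rows).
#' @export
cell_centers_x <- function(grid) {
  grid$x_min + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' @rdname cell_centers_x
#' @export
cell_centers_y <- function(grid) {
  grid$y_min + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$x_min, b$x_min)) && isTRUE(all.equal(a$y_min, b$y_min)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    a$n_cols == b$n_cols && a$n_rows == b$n_rows
}

#' Utilization-distribution raster
#'
#' Container pairing a [grid_spec()] with a matrix of per-cell values. For an
#' individual utilization distribution (UD) the values are probability mass
#' per cell and sum to 1; for the population-level surface they are summed
#' weighted mass and sum to the total of the aggregation weights.
#'
#' @param grid a `grid_spec`.
#' @param values numeric `n_rows x n_cols` matrix, nonnegative.
#' @param cat_id owner of the surface, or `"population"`.
#' @return an object of class `ud_raster`.
#' @export
ud_raster <- function(grid, values, cat_id = "population") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values matrix does not match grid dimensions")
  if (any(!is.finite(values)) || any(values < 0))
    stop("UD values must be finite and nonnegative")
  structure(list(grid = grid, values = values, cat_id = cat_id),
            class = "ud_raster")
}

#' @export
print.ud_raster <- function(x, ...) {
  cat(sprintf("ud_raster [%s]: %d x %d cells (%g m), total mass %.6g\n",
              x$cat_id, x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              sum(x$values)))
  invisible(x)
}

#' Build a grid covering a set of points
#'
#' Snaps a buffered bounding box of the points to whole cells. All cats in a
#' study share one such global grid so that aggregation needs no resampling.
#'
#' @param x,y point coordinates (m).
#' @param cell_size cell side (m).
#' @param buffer margin added on every side (m).
#' @param crs_tag CRS identifier carried through to outputs.
#' @return a `grid_spec` covering `[min - buffer, max + buffer]` in both axes.
#' @export
make_grid <- function(x, y, cell_size = 10, buffer = 100, crs_tag = "local") {
  stopifnot(length(x) > 0, length(x) == length(y), all(is.finite(c(x, y))))
  x0 <- floor((min(x) - buffer) / cell_size) * cell_size
  y0 <- floor((min(y) - buffer) / cell_size) * cell_size
  n_cols <- ceiling((max(x) + buffer - x0) / cell_size)
  n_rows <- ceiling((max(y) + buffer - y0) / cell_size)
  grid_spec(x0, y0, cell_size, max(n_cols, 1), max(n_rows, 1), crs_tag)
}
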