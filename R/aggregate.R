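#' Conservative re-gridding of UD rasters
#'
#' Resamples each raster to a template grid by area-weighted (conservative)
#' resampling: the mass of every source cell is distributed over the
#' template cells it overlaps, in proportion to overlap area. Per-raster
#' mass is preserved; a template that fails to cover a source raster (mass
#' loss above 1e-6 of the source mass) is an error, as is a fully disjoint
#' extent. Rasters already on the template pass through unchanged.
#'
#' When the whole study shares one global grid this is an identity, but the
#' operation supports mixing per-cat grids or resolutions.
#'
#' @param uds list of [ud_raster()].
#' @param template target `grid_spec`.
#' @return list of `ud_raster` on `template`.
#' @export
align_rasters <- function(uds, template) {
  stopifnot(inherits(template, "grid_spec"))
  lapply(uds, function(ud) {
    stopifnot(inherits(ud, "ud_raster"))
    if (grids_identical(ud$grid, template)) {
      ud$grid <- template
      return(ud)
    }
    rx <- overlap_fractions(template$x_min, template$cell_size, template$n_cols,
                            ud$grid$x_min, ud$grid$cell_size, ud$grid$n_cols)
    # y intervals of rows, north-first ordering on both sides
    ty0 <- template$y_min + (template$n_rows - seq_len(template$n_rows)) *
      template$cell_size
    sy0 <- ud$grid$y_min + (ud$grid$n_rows - seq_len(ud$grid$n_rows)) *
      ud$grid$cell_size
    ry <- overlap_fractions_at(ty0, template$cell_size, sy0, ud$grid$cell_size)
    if (all(rx == 0) || all(ry == 0))
      stop("raster extent is disjoint from the template grid")
    vals <- ry %*% ud$values %*% t(rx)
    lost <- sum(ud$values) - sum(vals)
    if (lost > 1e-6 * max(sum(ud$values), 1))
      stop("template grid does not cover raster ", ud$cat_id,
           "; mass lost: ", format(lost))
    ud_raster(template, pmax(vals, 0), cat_id = ud$cat_id)
  })
}

# fraction of source-cell extent overlapped by each template cell,
# for regular 1-D grids starting at t0/s0
overlap_fractions <- function(t0, tc, nt, s0, sc, ns) {
  ta <- t0 + (seq_len(nt) - 1) * tc
  sa <- s0 + (seq_len(ns) - 1) * sc
  m <- matrix(0, nt, ns)
  for (j in seq_len(nt)) {
    o <- pmin(ta[j] + tc, sa + sc) - pmax(ta[j], sa)
    m[j, ] <- pmax(o, 0) / sc
  }
  m
}

# same but with explicit interval start vectors (used for the y axis where
# row order runs north to south)
overlap_fractions_at <- function(ta, tc, sa, sc) {
  m <- matrix(0, length(ta), length(sa))
  for (j in seq_along(ta)) {
    o <- pmin(ta[j] + tc, sa + sc) - pmax(ta[j], sa)
    m[j, ] <- pmax(o, 0) / sc
  }
  m
}

#' Scale an individual UD by its outdoor weight
#'
#' Step two of the population aggregation: rescales a unit-mass individual
#' UD so its cells sum to `w`, the cat's average fraction of a day tracked
#' outdoors on days with data.
#'
#' @param ud a [ud_raster()] summing to 1.
#' @param w weight in `[0, 1]` (a number, or a row from [outdoor_weight()]).
#' @return the weighted `ud_raster` (sums to `w`).
#' @export
weight_ud <- function(ud, w) {
  stopifnot(inherits(ud, "ud_raster"))
  if (is.data.frame(w)) w <- w$w
  w <- as.numeric(w)
  if (!is.finite(w) || w < 0 || w > 1)
    stop("weight must lie in [0, 1]")
  if (abs(sum(ud$values) - 1) > 1e-6)
    stop("UD must sum to 1 before weighting")
  ud$values <- ud$values * w
  ud
}

#' Aggregate weighted UDs into a population-level surface
#'
#' Step three of the aggregation: cell-wise sum of the weighted individual
#' rasters. The result is deliberately *not* renormalized -- its total mass
#' equals the sum of the weights, so surfaces remain comparable between
#' populations (and between subsets of one population) in both magnitude and
#' shape.
#'
#' @param weighted_uds list of [ud_raster()] on one common grid, each
#'   already scaled by [weight_ud()].
#' @param weights optional named numeric of the weights used (recorded as
#'   provenance; defaults to each raster's cell sum).
#' @return object of class `catscape`: `raster` (a `ud_raster` with
#'   `cat_id = "population"`), `weights`, `grid`.
#' @export
aggregate_uds <- function(weighted_uds, weights = NULL) {
  stopifnot(length(weighted_uds) >= 1)
  grid <- weighted_uds[[1]]$grid
  for (ud in weighted_uds) {
    stopifnot(inherits(ud, "ud_raster"))
    if (!grids_identical(ud$grid, grid))
      stop("rasters are not on a common grid; align_rasters() first")
  }
  vals <- Reduce(`+`, lapply(weighted_uds, function(ud) ud$values))
  if (is.null(weights)) {
    weights <- vapply(weighted_uds, function(ud) sum(ud$values), numeric(1))
    names(weights) <- vapply(weighted_uds, function(ud) ud$cat_id, character(1))
  }
  structure(list(raster = ud_raster(grid, vals, cat_id = "population"),
                 weights = weights, grid = grid),
            class = "catscape")
}

#' @export
print.catscape <- function(x, ...) {
  cat(sprintf("catscape: %d cats, total mass %.4f (sum of weights %.4f)\n",
              length(x$weights), sum(x$raster$values), sum(x$weights)))
  print(x$grid)
  invisible(x)
}

# normalized copy of the population surface, for contour-based statistics
normalize_catscape <- function(cs) {
  stopifnot(inherits(cs, "catscape"))
  total <- sum(cs$raster$values)
  if (total <= 0) stop("catscape has no mass")
  ud_raster(cs$grid, cs$raster$values / total, cat_id = "population")
}
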