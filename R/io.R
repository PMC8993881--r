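#' Read home building footprints from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, one per cat, each with a
#' `cat_id` property (optional `sex`, `age_years`, `sterilized`). Coordinates
#' must be in the same projected meters as the fix data.
#'
#' @param path GeoJSON file path.
#' @return named list of study-cat entries: `cat_id`, `sex`, `age_years`,
#'   `sterilized`, `home_polygon` (vertex matrix), `home_point` (centroid).
#' @export
read_homes_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  out <- lapply(gj$features, function(f) {
    props <- f$properties
    if (is.null(props$cat_id)) stop("feature is missing the cat_id property")
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature for ", props$cat_id, " is not a Polygon")
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    colnames(poly) <- c("x", "y")
    poly <- validate_polygon(poly)
    study_cat(props$cat_id, home_polygon = poly,
              sex = props$sex %||% "unknown",
              age_years = props$age_years %||% NA_real_,
              sterilized = props$sterilized %||% NA)
  })
  names(out) <- vapply(out, function(h) h$cat_id, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Study-cat metadata entry
#'
#' @param cat_id cat identifier.
#' @param home_polygon building-footprint vertex matrix (validated).
#' @param sex `"F"`, `"M"` or `"unknown"`.
#' @param age_years age in years or `NA`.
#' @param sterilized logical or `NA`.
#' @return list of class `study_cat` with `home_point` set to the footprint
#'   centroid.
#' @export
study_cat <- function(cat_id, home_polygon, sex = "unknown",
                      age_years = NA_real_, sterilized = NA) {
  home_polygon <- validate_polygon(home_polygon)
  structure(list(cat_id = as.character(cat_id), sex = sex,
                 age_years = age_years, sterilized = sterilized,
                 home_polygon = home_polygon,
                 home_point = polygon_centroid(home_polygon)),
            class = "study_cat")
}

#' Write home footprints to GeoJSON
#'
#' @param homes named list of [study_cat()] entries.
#' @param path output path.
#' @export
write_homes_geojson <- function(homes, path) {
  feats <- lapply(homes, function(h) {
    ring <- rbind(h$home_polygon, h$home_polygon[1, ])
    list(type = "Feature",
         properties = list(cat_id = h$cat_id, sex = h$sex,
                           age_years = h$age_years,
                           sterilized = h$sterilized),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write land cover to GeoJSON
#'
#' One Polygon feature per polygon, with a `class` property.
#'
#' @param lc a [landcover()].
#' @param path output path.
#' @export
write_landcover_geojson <- function(lc, path) {
  feats <- list()
  for (nm in names(lc$classes)) {
    for (poly in lc$classes[[nm]]) {
      ring <- rbind(as_ring(poly), as_ring(poly)[1, ])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature", properties = list(class = nm),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                          function(i) as.numeric(ring[i, ])))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read land cover from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygon features with a `class`
#'   property.
#' @param urban_classes classes counted as developed (default `urban`,
#'   `developed`).
#' @return a [landcover()].
#' @export
read_landcover_geojson <- function(path, urban_classes = c("urban", "developed")) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  classes <- list()
  for (f in gj$features) {
    nm <- f$properties$class %||% "other"
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    colnames(poly) <- c("x", "y")
    classes[[nm]] <- c(classes[[nm]], list(poly))
  }
  landcover(classes, urban_classes = intersect(urban_classes, names(classes)))
}

#' Write volume contours to GeoJSON
#'
#' Each contour becomes one MultiPolygon feature with properties `level`,
#' `area_ha` and `cat_id`.
#'
#' @param contours named list of [volume_contour()] (e.g. from
#'   [home_range_summary()]).
#' @param path output path.
#' @param cat_id identifier recorded on each feature.
#' @export
write_contours_geojson <- function(contours, path, cat_id = "population") {
  feats <- lapply(contours, function(cc) {
    polys <- lapply(cc$polygons, function(p) {
      ring <- rbind(p, p[1, ])
      list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
    })
    list(type = "Feature",
         properties = list(level = cc$level, area_ha = cc$area_ha,
                           cat_id = cat_id),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write rasters as ESRI ASCII grid
#'
#' Plain-text georeferenced raster interchange (readable by any GIS). Rows
#' are written north to south, matching the in-memory matrix layout.
#'
#' @param ud a [ud_raster()] (or `catscape`, whose raster is written).
#' @param path output `.asc` path.
#' @export
write_asc_raster <- function(ud, path) {
  if (inherits(ud, "catscape")) ud <- ud$raster
  stopifnot(inherits(ud, "ud_raster"))
  g <- ud$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$x_min),
    sprintf("yllcorner %.10g", g$y_min),
    sprintf("cellsize %.10g", g$cell_size),
    "NODATA_value -9999"
  ), con)
  utils::write.table(format(ud$values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_asc_raster
#' @param crs_tag CRS identifier to record on the returned raster.
#' @param cat_id identifier for the returned raster.
#' @export
read_asc_raster <- function(path, crs_tag = "local", cat_id = "population") {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- tolower(vapply(kv, `[`, character(1), 1))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  grid <- grid_spec(vals[["xllcorner"]], vals[["yllcorner"]],
                    vals[["cellsize"]], vals[["ncols"]], vals[["nrows"]],
                    crs_tag = crs_tag)
  ud_raster(grid, m, cat_id = cat_id)
}

#' Read per-cat download dates from a YAML sidecar
#'
#' The file maps `cat_id` to a vector of ISO dates on which the GPS unit was
#' retrieved for data download.
#'
#' @param path YAML file path.
#' @return named list of `Date` vectors.
#' @export
read_download_dates <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) as.Date(unlist(x)))
}
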