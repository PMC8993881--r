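#' Default pipeline configuration
#'
#' All tunable parameters of [run_pipeline()] with their defaults. Any
#' subset can be overridden through the `config` argument; the full merged
#' configuration is recorded in the run manifest.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    min_elev = 0, max_elev = 300,     # plausible elevation band, m
    first_days = 2,                   # collar-habituation days dropped
    max_ehpe = 5000,                  # fixes with EHPE >= this are dropped
    thin_interval = 120,              # s, minimum fix interval for BBMM
    cluster_radius = 10,              # m, sequential-cluster radius
    cluster_window = 24 * 3600,       # s, cluster time window
    cluster_min_points = 2,
    gap_cap = 1800,                   # s, per-gap cap in daily coverage
    location_error = 5,               # m, BBMM position error SD (device
                                      # error scale; nominal error < 10 m)
    max_lag = 3600,                   # s, longest bridged gap
    cell_size = 10,                   # m, global grid resolution
    n_alpha = 50,                     # bridge integration points
    levels = c(0.5, 0.95, 0.99),      # home-range contour levels
    min_tracking_days = 5,            # inclusion rule: days with data
    min_fixes = 3,                    # inclusion rule: post-filter fixes
    near_radius = 50,                 # m, near-home radius
    ring_radius = 100,                # m, outer annulus radius
    contour_level = 0.99,             # population-surface delineation
    grid_buffer_cap = 500             # m, cap on the automatic grid margin
  )
}

#' Run the full catscape pipeline
#'
#' Executes the whole analysis: pre-processing filters, indoor-cluster
#' excision, daily-coverage weights, thinning, Brownian-bridge motion
#' variance and utilization distribution per cat on one shared global grid,
#' weighting and aggregation into the population surface, and all spatial
#' summary statistics. Cats with too few tracking days or fixes after
#' filtering are excluded and logged in the manifest. The pipeline itself
#' is fully deterministic.
#'
#' The shared grid covers the bounding box of all outdoor fixes plus an
#' automatic margin of three 95% bridge radii at the largest estimated
#' motion variance over a one-hour bridge, capped at `grid_buffer_cap`.
#'
#' @param tracks named list of [cat_track()] or path to a fixes CSV
#'   (see [read_tracks()]).
#' @param homes named list of [study_cat()] or path to a homes GeoJSON.
#' @param lc optional [landcover()] or path to a land-cover GeoJSON.
#' @param config named list overriding entries of [default_config()].
#' @param out_dir optional directory; when given, writes `summary_per_cat.csv`,
#'   `summary_population.csv`, `catscape.asc`, `contours.geojson` and
#'   `manifest.yaml`.
#' @return object of class `catscape_run`: `catscape`, `per_cat` and
#'   `population` summary data frames, `uds`, `weights`, `contours`
#'   (population-level), `grid`, `excluded`, `manifest`.
#' @export
run_pipeline <- function(tracks, homes, lc = NULL, config = list(),
                         out_dir = NULL) {
  if (is.character(tracks)) tracks <- read_tracks(tracks)
  if (is.character(homes)) homes <- read_homes_geojson(homes)
  if (is.character(lc)) lc <- read_landcover_geojson(lc)
  cfg <- utils::modifyList(default_config(), config)

  excluded <- list()
  exclude <- function(id, why) excluded[[id]] <<- why

  prepared <- list()
  for (id in names(tracks)) {
    if (is.null(homes[[id]])) { exclude(id, "no home footprint"); next }
    tr <- tracks[[id]]
    tr <- filter_elevation(tr, cfg$min_elev, cfg$max_elev)
    tr <- filter_first_days(tr, cfg$first_days)
    tr <- filter_download_days(tr)
    tr <- filter_ehpe(tr, cfg$max_ehpe)
    n_raw <- nrow(tracks[[id]]$fixes)
    cl <- find_sequential_clusters(tr, cfg$cluster_radius,
                                   cfg$cluster_window, cfg$cluster_min_points)
    tr <- remove_home_clusters(tr, cl, homes[[id]]$home_polygon)
    if (nrow(tr$fixes) < cfg$min_fixes) {
      exclude(id, sprintf("only %d outdoor fixes after filtering",
                          nrow(tr$fixes)))
      next
    }
    cov <- daily_coverage(tr, cfg$gap_cap)
    if (nrow(cov) < cfg$min_tracking_days) {
      exclude(id, sprintf("only %d tracking days (minimum %d)",
                          nrow(cov), cfg$min_tracking_days))
      next
    }
    thinned <- thin_track(tr, cfg$thin_interval)
    if (nrow(thinned$fixes) < 3) {
      exclude(id, "fewer than 3 fixes after thinning")
      next
    }
    mv <- tryCatch(
      estimate_motion_variance(thinned, cfg$location_error, cfg$max_lag),
      error = function(e) NULL)
    if (is.null(mv)) { exclude(id, "motion variance not estimable"); next }
    prepared[[id]] <- list(outdoor = tr, thinned = thinned, mv = mv,
                           weight = outdoor_weight(cov), n_raw = n_raw,
                           n_days = nrow(cov))
  }
  if (!length(prepared)) stop("no usable cats after filtering and exclusions")

  # shared global grid
  all_x <- unlist(lapply(prepared, function(p) p$thinned$fixes$x))
  all_y <- unlist(lapply(prepared, function(p) p$thinned$fixes$y))
  max_s2 <- max(vapply(prepared, function(p) p$mv$sigma2_m, numeric(1)))
  r95 <- sqrt(stats::qchisq(0.95, 2) * (3600 * 0.25 * max_s2 +
                                          cfg$location_error^2))
  buffer <- max(50, min(3 * r95, cfg$grid_buffer_cap))
  grid <- make_grid(all_x, all_y, cfg$cell_size, buffer,
                    crs_tag = tracks[[names(prepared)[1]]]$crs_tag)

  uds <- list(); weighted <- list(); weights <- numeric()
  per_cat_rows <- list()
  for (id in names(prepared)) {
    p <- prepared[[id]]
    ud <- compute_ud(p$thinned, p$mv, cfg$location_error, grid,
                     cfg$max_lag, cfg$n_alpha)
    hr <- home_range_summary(ud, cfg$levels)
    ds <- distance_stats(p$outdoor, homes[[id]]$home_point, cfg$near_radius)
    frac95_nonurban <- NA_real_
    if (!is.null(lc) && 0.95 %in% cfg$levels) {
      m95 <- hr$contours[["0.95"]]$mask
      frac95_nonurban <- sum(m95 & !urban_mask(grid, lc)) / sum(m95)
    }
    uds[[id]] <- ud
    weights[id] <- p$weight$w
    weighted[[id]] <- weight_ud(ud, p$weight$w)
    area_cols <- as.list(hr$areas$area_ha)
    names(area_cols) <- sprintf("area%02.0f_ha", hr$areas$level * 100)
    per_cat_rows[[id]] <- data.frame(
      cat_id = id, n_fixes_raw = p$n_raw,
      n_fixes_outdoor = nrow(p$outdoor$fixes),
      n_tracking_days = p$n_days, w = p$weight$w,
      sigma2_m2min = p$mv$sigma2_m * 60,
      as.data.frame(area_cols),
      mean_dist_m = ds$mean_dist_m, max_dist_m = ds$max_dist_m,
      frac_within_50m = ds$frac_within,
      frac95_nonurban = frac95_nonurban)
  }
  per_cat <- do.call(rbind, per_cat_rows)
  rownames(per_cat) <- NULL

  cs <- aggregate_uds(align_rasters(weighted, grid), weights = weights)
  pop_ud <- normalize_catscape(cs)
  pop_contours <- lapply(cfg$levels, function(l) volume_contour(pop_ud, l))
  names(pop_contours) <- sprintf("%g", cfg$levels)
  cl99 <- sprintf("%g", cfg$contour_level)
  area99 <- if (cl99 %in% names(pop_contours)) pop_contours[[cl99]]$area_ha
            else volume_contour(pop_ud, cfg$contour_level)$area_ha
  part <- if (!is.null(lc)) landcover_partition(cs, lc, cfg$contour_level)
          else list(fraction_area_outside = NA_real_,
                    fraction_intensity_outside = NA_real_)
  population <- data.frame(
    n_cats = length(prepared),
    sum_weights = sum(weights),
    catscape_mass = sum(cs$raster$values),
    contour_area_ha = area99,
    contour_level = cfg$contour_level,
    fold_range = intensity_fold_range(cs, cfg$contour_level),
    near_home_ratio = near_home_intensity_ratio(
      cs, homes[names(prepared)], cfg$near_radius, cfg$ring_radius),
    frac_area_outside_urban = part$fraction_area_outside,
    frac_intensity_outside_urban = part$fraction_intensity_outside)

  manifest <- list(
    package = as.character(utils::packageVersion("catscape")),
    config = cfg,
    grid = list(x_min = grid$x_min, y_min = grid$y_min,
                cell_size = grid$cell_size, n_cols = grid$n_cols,
                n_rows = grid$n_rows, crs_tag = grid$crs_tag,
                buffer_m = buffer),
    cats_included = names(prepared),
    cats_excluded = lapply(excluded, identity))

  run <- structure(list(catscape = cs, per_cat = per_cat,
                        population = population, uds = uds,
                        weights = weights, contours = pop_contours,
                        grid = grid, excluded = excluded,
                        manifest = manifest),
                   class = "catscape_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.catscape_run <- function(x, ...) {
  cat(sprintf("catscape_run: %d cats included, %d excluded\n",
              nrow(x$per_cat), length(x$excluded)))
  cat(sprintf("  population mass %.4f over a %.2f-ha %g%% contour\n",
              x$population$catscape_mass, x$population$contour_area_ha,
              x$population$contour_level * 100))
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Writes the stable-format outputs of a [run_pipeline()] result:
#' `summary_per_cat.csv`, `summary_population.csv` (column order as in the
#' returned data frames), `catscape.asc` (ESRI ASCII grid),
#' `contours.geojson` (population-level contours) and `manifest.yaml`.
#'
#' @param run a `catscape_run`.
#' @param out_dir output directory (created if needed).
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$per_cat, file.path(out_dir, "summary_per_cat.csv"),
                   row.names = FALSE)
  utils::write.csv(run$population,
                   file.path(out_dir, "summary_population.csv"),
                   row.names = FALSE)
  write_asc_raster(run$catscape, file.path(out_dir, "catscape.asc"))
  write_contours_geojson(run$contours, file.path(out_dir, "contours.geojson"))
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
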