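#' Configuration for the synthetic cat-population generator
#'
#' Defaults emulate a month-long neighbourhood tracking study: 30-s fix
#' interval over 28 days starting May 1, homes on a jittered grid inside an
#' urban polygon, home-anchored (mean-reverting) outdoor movement with
#' several hours outdoors per day, occasional indoor bouts from collars left
#' on, Gaussian position error, rare device-error outliers, and missing
#' tracking days. See the methods vignette for the reasoning behind each
#' default.
#'
#' @param n_cats number of cats (default 12, a neighbourhood-scale example
#'   population).
#' @param study_days tracking days (default 28).
#' @param start_date first tracking day (local), default `"2021-05-01"`.
#' @param fix_interval_s nominal fix interval in seconds (default 30).
#' @param home_spacing mean nearest-neighbour distance between homes, m.
#' @param home_footprint building-footprint square side, m (default 10).
#' @param sigma2_m_range per-cat Brownian motion variance range, m^2/min.
#' @param attraction_rate mean-reversion rate toward home, 1/min. With the
#'   default variances this puts the stationary spread of outdoor activity
#'   at roughly 30 m SD around the home, i.e. most fixes within 50 m.
#' @param excursion_hours_per_day_range daily outdoor hours, drawn uniform.
#' @param excursion_center_offset `(dx, dy)` of the outdoor activity centre
#'   relative to the home (default `c(0, 0)`; useful for fixtures that need
#'   outdoor fixes well away from the footprint).
#' @param indoor_bout_fraction probability per tracked day of an indoor bout
#'   (collar left on inside).
#' @param gps_error_sd_m isotropic Gaussian observation error SD, m.
#' @param ehpe_outlier_rate per-fix probability of an EHPE >= 5000 outlier.
#' @param elevation_base_m nominal elevation of the study area, m.
#' @param elevation_outlier_rate per-fix probability of an out-of-range
#'   elevation glitch.
#' @param missing_day_prob probability a day has no tracking data.
#' @param download_day study day on which units were retrieved for download
#'   (fixes exist but the day is flagged; `NA` for none).
#' @param two_cat_household_frac fraction of households with two cats.
#' @param pure_brownian if `TRUE`, outdoor movement is pure (non-reverting)
#'   Brownian motion -- the exact model the bridge estimator assumes; used
#'   for parameter-recovery checks.
#' @param tz local time zone for day boundaries.
#' @param seed integer master seed; the full output stream is a pure
#'   function of it, and per-cat substreams are split so adding a cat never
#'   perturbs existing cats' data.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cats = 12, study_days = 28, start_date = "2021-05-01",
                       fix_interval_s = 30, home_spacing = 80,
                       home_footprint = 10, sigma2_m_range = c(10, 40),
                       attraction_rate = 0.012,
                       excursion_hours_per_day_range = c(5.6, 11.2),
                       excursion_center_offset = c(0, 0),
                       indoor_bout_fraction = 0.3, gps_error_sd_m = 5,
                       ehpe_outlier_rate = 0.02, elevation_base_m = 100,
                       elevation_outlier_rate = 0.01, missing_day_prob = 0.15,
                       download_day = 11, two_cat_household_frac = 0.18,
                       pure_brownian = FALSE, tz = "Etc/GMT-2", seed = 1) {
  cfg <- list(n_cats = n_cats, study_days = study_days,
              start_date = as.Date(start_date),
              fix_interval_s = fix_interval_s, home_spacing = home_spacing,
              home_footprint = home_footprint,
              sigma2_m_range = sigma2_m_range,
              attraction_rate = attraction_rate,
              excursion_hours_per_day_range = excursion_hours_per_day_range,
              excursion_center_offset = excursion_center_offset,
              indoor_bout_fraction = indoor_bout_fraction,
              gps_error_sd_m = gps_error_sd_m,
              ehpe_outlier_rate = ehpe_outlier_rate,
              elevation_base_m = elevation_base_m,
              elevation_outlier_rate = elevation_outlier_rate,
              missing_day_prob = missing_day_prob,
              download_day = download_day,
              two_cat_household_frac = two_cat_household_frac,
              pure_brownian = isTRUE(pure_brownian), tz = tz,
              seed = as.integer(seed))
  stopifnot(cfg$n_cats >= 1, cfg$study_days >= 1, cfg$fix_interval_s > 0,
            cfg$home_spacing > 0, cfg$home_footprint > 0,
            length(cfg$sigma2_m_range) == 2, all(cfg$sigma2_m_range > 0),
            cfg$attraction_rate > 0,
            length(cfg$excursion_hours_per_day_range) == 2,
            all(cfg$excursion_hours_per_day_range > 0),
            cfg$excursion_hours_per_day_range[2] <= 18,
            cfg$indoor_bout_fraction >= 0, cfg$indoor_bout_fraction <= 1,
            cfg$gps_error_sd_m >= 0,
            cfg$ehpe_outlier_rate >= 0, cfg$ehpe_outlier_rate <= 1,
            cfg$elevation_outlier_rate >= 0, cfg$elevation_outlier_rate <= 1,
            cfg$missing_day_prob >= 0, cfg$missing_day_prob < 1,
            cfg$two_cat_household_frac >= 0, cfg$two_cat_household_frac <= 1)
  structure(cfg, class = "sim_config")
}

# derived per-entity seeds, kept well below 2^31
cat_seed <- function(cfg, i) (cfg$seed %% 100000L) * 10000L + 1000000L + i
household_seed <- function(cfg, h) (cfg$seed %% 100000L) * 10000L + 5000000L + h

#' Simulate one cat's GPS track
#'
#' Outdoor movement is an Ornstein-Uhlenbeck (mean-reverting) walk toward
#' the home (exact discretization at the fix interval), so home ranges are
#' bounded like a real cat's; with `pure_brownian = TRUE` it is unanchored
#' Brownian motion, the exact generating model of the bridge estimator.
#' Outdoor positions falling inside the building footprint are pushed just
#' outside the nearest wall (a cat outdoors is not inside the house).
#' Fixes are emitted at the fix interval during one outdoor excursion per
#' tracked day; with probability `indoor_bout_fraction` an indoor bout (a
#' tight cluster of fixes jittered within 1 m inside the footprint) follows
#' the excursion, emulating collars left on indoors. Observation error,
#' EHPE outliers, elevation glitches, missing days and the download-day flag
#' give every pre-processing filter work to do.
#'
#' @param cat_id identifier.
#' @param home_point numeric `(x, y)` of the home centre (m).
#' @param cfg a [sim_config()].
#' @param seed integer seed for this cat's private stream.
#' @return list with `track` (a [cat_track()]), `home` (a [study_cat()]) and
#'   `truth`: `sigma2_m` (m^2/s), `home_point`, `outdoor_hours` (per tracked
#'   day), `frac_within_50m` (of emitted outdoor fixes), `indoor` (logical
#'   per fix), `n_ehpe_outliers`, `n_elev_outliers`.
#' @export
simulate_cat <- function(cat_id, home_point, cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  sigma2_min <- stats::runif(1, cfg$sigma2_m_range[1], cfg$sigma2_m_range[2])
  s2 <- sigma2_min / 60                       # m^2/s
  a <- cfg$attraction_rate / 60               # 1/s
  dt <- cfg$fix_interval_s
  h <- cfg$home_footprint / 2
  center <- home_point + cfg$excursion_center_offset
  day0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = cfg$tz)

  rows <- list()
  truth_hours <- numeric()
  for (d in seq_len(cfg$study_days)) {
    if (stats::runif(1) < cfg$missing_day_prob) next
    hours <- stats::runif(1, cfg$excursion_hours_per_day_range[1],
                          cfg$excursion_hours_per_day_range[2])
    start_h <- 6 + stats::runif(1) * max(0.01, 15 - hours)
    n_fix <- floor(hours * 3600 / dt) + 1
    t0 <- day0 + (d - 1) * 86400 + start_h * 3600
    times <- t0 + (seq_len(n_fix) - 1) * dt

    if (cfg$pure_brownian) {
      ex <- cumsum(c(0, stats::rnorm(n_fix - 1, 0, sqrt(s2 * dt))))
      ey <- cumsum(c(0, stats::rnorm(n_fix - 1, 0, sqrt(s2 * dt))))
    } else {
      sd_st <- sqrt(s2 / (2 * a))
      phi <- exp(-a * dt)
      sd_in <- sd_st * sqrt(1 - phi^2)
      e0 <- stats::rnorm(2, 0, sd_st)
      ex <- as.numeric(stats::filter(stats::rnorm(n_fix - 1, 0, sd_in),
                                     phi, "recursive", init = e0[1]))
      ey <- as.numeric(stats::filter(stats::rnorm(n_fix - 1, 0, sd_in),
                                     phi, "recursive", init = e0[2]))
      ex <- c(e0[1], ex); ey <- c(e0[2], ey)
    }
    px <- center[1] + ex
    py <- center[2] + ey
    # keep outdoor positions out of the building footprint
    inside <- abs(px - home_point[1]) < h & abs(py - home_point[2]) < h
    if (any(inside)) {
      dx <- px[inside] - home_point[1]
      dy <- py[inside] - home_point[2]
      push_x <- abs(dx) >= abs(dy)
      dx[push_x] <- sign(dx[push_x] + 1e-12) * (h + 0.5)
      dy[!push_x] <- sign(dy[!push_x] + 1e-12) * (h + 0.5)
      px[inside] <- home_point[1] + dx
      py[inside] <- home_point[2] + dy
    }
    ox <- px + stats::rnorm(n_fix, 0, cfg$gps_error_sd_m)
    oy <- py + stats::rnorm(n_fix, 0, cfg$gps_error_sd_m)

    day_rows <- data.frame(
      timestamp = times, x = ox, y = oy,
      elevation = cfg$elevation_base_m + stats::rnorm(n_fix, 0, 3),
      ehpe = pmin(abs(stats::rnorm(n_fix, 8, 3)), 100),
      indoor = FALSE)
    truth_hours <- c(truth_hours, (n_fix - 1) * dt / 3600)

    if (stats::runif(1) < cfg$indoor_bout_fraction) {
      dur <- stats::runif(1, 0.5, 2)
      b0 <- times[n_fix] + 1800
      day_end <- day0 + d * 86400 - dt
      n_in <- floor(min(dur * 3600, as.numeric(day_end - b0, units = "secs")) / dt) + 1
      if (n_in >= 2) {
        jit <- min(1, h)
        day_rows <- rbind(day_rows, data.frame(
          timestamp = b0 + (seq_len(n_in) - 1) * dt,
          x = home_point[1] + stats::runif(n_in, -jit, jit),
          y = home_point[2] + stats::runif(n_in, -jit, jit),
          elevation = cfg$elevation_base_m + stats::rnorm(n_in, 0, 3),
          ehpe = pmin(abs(stats::rnorm(n_in, 8, 3)), 100),
          indoor = TRUE))
      }
    }
    rows[[length(rows) + 1L]] <- day_rows
  }
  if (!length(rows)) stop("simulated cat ", cat_id, " has no tracked days")
  df <- do.call(rbind, rows)

  # planted device-error outliers (drawn after assembly, one pass each)
  n <- nrow(df)
  ehpe_out <- stats::runif(n) < cfg$ehpe_outlier_rate
  df$ehpe[ehpe_out] <- 5000 + stats::rexp(sum(ehpe_out), 1 / 500)
  elev_out <- stats::runif(n) < cfg$elevation_outlier_rate
  df$elevation[elev_out] <- sample(c(-15, 350), sum(elev_out), replace = TRUE)

  dl <- if (!is.na(cfg$download_day) && cfg$download_day <= cfg$study_days)
    cfg$start_date + cfg$download_day - 1 else as.Date(character())
  track <- cat_track(cat_id, df[c("timestamp", "x", "y", "elevation", "ehpe")],
                     deployment_start = cfg$start_date, download_dates = dl,
                     crs_tag = "local", tz = cfg$tz)
  outdoor <- !df$indoor
  d_home <- sqrt((df$x - home_point[1])^2 + (df$y - home_point[2])^2)
  truth <- list(
    cat_id = as.character(cat_id), home_point = home_point,
    sigma2_m = s2, sigma2_m2min = sigma2_min,
    outdoor_hours = truth_hours,
    frac_within_50m = mean(d_home[outdoor] <= 50),
    indoor = df$indoor,
    n_ehpe_outliers = sum(df$ehpe >= 5000),
    n_elev_outliers = sum(df$elevation < 0 | df$elevation > 300))
  home <- study_cat(cat_id,
                    square_polygon(home_point[1], home_point[2],
                                   cfg$home_footprint))
  list(track = track, home = home, truth = truth)
}

#' Simulate a neighbourhood cat population
#'
#' Places households on a jittered grid (a fixed-width column layout, so
#' enlarging the population only appends homes), assigns one or two cats per
#' household, simulates each cat with its own random substream, and wraps
#' the urban block in a land-cover map (an `urban` rectangle with 100-m
#' margin inside a larger `other` frame). Outputs feed [run_pipeline()]
#' directly, or can be written to disk with the `write_*` helpers.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_population`: `tracks` (named list of
#'   [cat_track()]), `homes` (named list of [study_cat()]), `landcover`
#'   (a [landcover()]), `truth` (named per-cat list), `config`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  grid_cols <- 6L
  # households until all cats are placed; composition per household is
  # seeded independently so the assignment is stable under growth
  cats_left <- cfg$n_cats
  homes_xy <- list(); cats_per_house <- integer()
  hh <- 0L
  while (cats_left > 0L) {
    hh <- hh + 1L
    set.seed(household_seed(cfg, hh))
    nh <- 1L + (stats::runif(1) < cfg$two_cat_household_frac)
    nh <- min(nh, cats_left)
    jit <- stats::runif(2, -0.25, 0.25) * cfg$home_spacing
    col <- (hh - 1L) %% grid_cols
    row <- (hh - 1L) %/% grid_cols
    homes_xy[[hh]] <- c(col, row) * cfg$home_spacing + jit
    cats_per_house[hh] <- nh
    cats_left <- cats_left - nh
  }

  tracks <- list(); homes <- list(); truth <- list()
  i <- 0L
  for (hcur in seq_len(hh)) {
    for (k in seq_len(cats_per_house[hcur])) {
      i <- i + 1L
      id <- sprintf("cat%02d", i)
      sim <- simulate_cat(id, homes_xy[[hcur]], cfg, cat_seed(cfg, i))
      tracks[[id]] <- sim$track
      homes[[id]] <- sim$home
      truth[[id]] <- sim$truth
    }
  }

  pts <- do.call(rbind, homes_xy)
  urban <- cbind(x = c(min(pts[, 1]) - 100, max(pts[, 1]) + 100,
                       max(pts[, 1]) + 100, min(pts[, 1]) - 100),
                 y = c(min(pts[, 2]) - 100, min(pts[, 2]) - 100,
                       max(pts[, 2]) + 100, max(pts[, 2]) + 100))
  other <- cbind(x = c(min(pts[, 1]) - 600, max(pts[, 1]) + 600,
                       max(pts[, 1]) + 600, min(pts[, 1]) - 600),
                 y = c(min(pts[, 2]) - 600, min(pts[, 2]) - 600,
                       max(pts[, 2]) + 600, max(pts[, 2]) + 600))
  lc <- landcover(list(urban = list(urban), other = list(other)),
                  urban_classes = "urban")
  structure(list(tracks = tracks, homes = homes, landcover = lc,
                 truth = truth, config = cfg),
            class = "sim_population")
}

#' Expected stationary population intensity of a simulated population
#'
#' Analytic long-run intensity surface implied by the generator: each cat
#' contributes its true outdoor weight times the stationary Gaussian of its
#' mean-reverting outdoor process (variance `sigma2 / (2 a)` per axis plus
#' observation error), evaluated as mass per cell. Useful as ground truth
#' for population-surface checks; only meaningful for the mean-reverting
#' (default) movement mode.
#'
#' @param pop a `sim_population`.
#' @param grid `grid_spec` on which to evaluate.
#' @return a [ud_raster()] (total mass = sum of true weights).
#' @export
expected_population_intensity <- function(pop, grid) {
  cfg <- pop$config
  a <- cfg$attraction_rate / 60
  cx <- cell_centers_x(grid); cy <- cell_centers_y(grid)
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  for (tr in pop$truth) {
    v <- tr$sigma2_m / (2 * a) + cfg$gps_error_sd_m^2
    w <- mean(tr$outdoor_hours / 24)
    ctr <- tr$home_point + cfg$excursion_center_offset
    gx <- stats::dnorm(cx, ctr[1], sqrt(v))
    gy <- stats::dnorm(cy, ctr[2], sqrt(v))
    vals <- vals + w * outer(gy, gx) * grid$cell_size^2
  }
  ud_raster(grid, vals, cat_id = "population")
}
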