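# Fixture builders and independent oracles used across the suite.
# Everything is generated in code; no data files.

fix_origin <- as.POSIXct("2021-05-03 00:00:00", tz = "UTC")

make_fixes <- function(t_sec, x, y, elevation = 100, ehpe = 5,
                       origin = fix_origin) {
  data.frame(timestamp = origin + t_sec, x = x, y = y,
             elevation = elevation, ehpe = ehpe)
}

toy_track <- function(t_sec, x, y, elevation = 100, ehpe = 5,
                      cat_id = "toy", ...) {
  cat_track(cat_id, make_fixes(t_sec, x, y, elevation, ehpe), ...)
}

# discrete isotropic Gaussian UD centred on the grid (mass per cell,
# normalized to 1)
gaussian_ud <- function(sigma = 50, cell = 1, half = 250, center = c(0, 0),
                        cat_id = "gauss", grid = NULL) {
  if (is.null(grid)) {
    n <- ceiling(2 * half / cell)
    grid <- grid_spec(center[1] - half, center[2] - half, cell, n, n)
  }
  gx <- dnorm(cell_centers_x(grid), center[1], sigma)
  gy <- dnorm(cell_centers_y(grid), center[2], sigma)
  vals <- outer(gy, gx) * cell^2
  ud_raster(grid, vals / sum(vals), cat_id = cat_id)
}

# --- independent oracles ------------------------------------------------

# greedy thinning oracle: plain loop, separate from the implementation
thin_oracle_times <- function(t_sec, min_interval) {
  kept <- t_sec[1]
  last <- t_sec[1]
  for (tt in t_sec[-1]) {
    if (tt >= last + min_interval) { kept <- c(kept, tt); last <- tt }
  }
  kept
}

# adaptive-quadrature oracle for a single-segment bridge UD: integrates the
# bridge density over alpha independently per cell, then normalizes like
# compute_ud does
bridge_quadrature_oracle <- function(p1, p2, dt, sigma2, delta, grid) {
  cx <- cell_centers_x(grid)
  cy <- cell_centers_y(grid)
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      f <- function(a) {
        v <- dt * a * (1 - a) * sigma2 + ((1 - a)^2 + a^2) * delta^2
        mx <- p1[1] + a * (p2[1] - p1[1])
        my <- p1[2] + a * (p2[2] - p1[2])
        exp(-((cx[j] - mx)^2 + (cy[i] - my)^2) / (2 * v)) / (2 * pi * v)
      }
      vals[i, j] <- stats::integrate(f, 0, 1, rel.tol = 1e-12,
                                     abs.tol = 1e-15)$value
    }
  }
  vals <- vals * grid$cell_size^2
  vals / sum(vals)
}

# negative log-likelihood of the leave-one-out triplets, written
# independently of the package internals (plain loop over triplets)
loo_nll_oracle <- function(track, sigma2, delta, max_lag = 3600) {
  ts <- as.numeric(track$fixes$timestamp)
  x <- track$fixes$x; y <- track$fixes$y
  total <- 0
  for (i in seq(2, nrow(track$fixes) - 1, by = 2)) {
    if (ts[i] - ts[i - 1] > max_lag || ts[i + 1] - ts[i] > max_lag) next
    tsp <- ts[i + 1] - ts[i - 1]
    a <- (ts[i] - ts[i - 1]) / tsp
    mx <- x[i - 1] + a * (x[i + 1] - x[i - 1])
    my <- y[i - 1] + a * (y[i + 1] - y[i - 1])
    v <- tsp * a * (1 - a) * sigma2 + ((1 - a)^2 + a^2 + 1) * delta^2
    total <- total + log(2 * pi * v) +
      ((x[i] - mx)^2 + (y[i] - my)^2) / (2 * v)
  }
  total
}

# volume-contour oracle: pick the largest threshold whose super-level set
# reaches the mass level (threshold enumeration, not sorting)
contour_mask_oracle <- function(values, level) {
  cand <- sort(unique(values[values > 0]), decreasing = TRUE)
  for (thr in cand) {
    if (sum(values[values >= thr]) >= level * sum(values) - 1e-12)
      return(values >= thr & values > 0)
  }
  values > 0
}

# --- planted-violation fixture -----------------------------------------
# 200 fixes, deployment 2021-05-01, download day 2021-05-05; each filter
# has an exactly known removal count and the planted categories do not
# overlap.
planted_filter_fixture <- function() {
  tz <- "Etc/GMT-2"
  day <- function(d) as.POSIXct(sprintf("2021-05-%02d 10:00:00", d), tz = tz)
  ts <- c(day(1) + 30 * (0:11),     # 12 fixes on day 1   (first-days)
          day(2) + 30 * (0:7),      #  8 fixes on day 2   (first-days)
          day(5) + 30 * (0:11),     # 12 fixes on day 5   (download day)
          day(3) + 30 * (0:99),     # 100 clean fixes
          day(4) + 30 * (0:51),     # 52 clean + 7 elevation + 9 ehpe below
          day(6) + 30 * (0:15))
  n <- length(ts)                   # 200
  stopifnot(n == 200)
  elevation <- rep(100, n)
  ehpe <- rep(5, n)
  # plant violations among the day-4 block (indices 133:184)
  elev_idx <- 133:139               # 7 fixes out of range
  ehpe_idx <- 140:148               # 9 fixes with ehpe >= 5000
  elevation[elev_idx] <- c(-5, -1, 301, 310, 350, -20, 400)
  ehpe[ehpe_idx] <- c(5000, 5001, 6000, 9999, 5000, 7500, 5200, 8000, 5050)
  o <- order(ts)
  tr <- cat_track("planted", data.frame(timestamp = ts, x = seq_len(n),
                                        y = 0, elevation = elevation,
                                        ehpe = ehpe)[o, ],
                  deployment_start = as.Date("2021-05-01"),
                  download_dates = as.Date("2021-05-05"), tz = tz)
  list(track = tr, n = n, n_first_days = 20, n_download = 12,
       n_elev = 7, n_ehpe = 9)
}

# config whose outdoor activity stays ~80 m from the home, so indoor-bout
# membership is unambiguous for the excision exactness checks
separated_bouts_config <- function(seed = 1, study_days = 12) {
  sim_config(n_cats = 1, study_days = study_days,
             excursion_center_offset = c(80, 0),
             attraction_rate = 0.5, sigma2_m_range = c(5, 5),
             indoor_bout_fraction = 1, ehpe_outlier_rate = 0,
             elevation_outlier_rate = 0, missing_day_prob = 0.1,
             seed = seed)
}

# --- shared default-population pipeline run (memoised) ------------------
.pipeline_cache <- new.env(parent = emptyenv())

default_population <- function() {
  if (is.null(.pipeline_cache$pop))
    .pipeline_cache$pop <- simulate_population(sim_config(seed = 42))
  .pipeline_cache$pop
}

default_run <- function() {
  if (is.null(.pipeline_cache$run)) {
    pop <- default_population()
    .pipeline_cache$run <- run_pipeline(pop$tracks, pop$homes, pop$landcover)
  }
  .pipeline_cache$run
}
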