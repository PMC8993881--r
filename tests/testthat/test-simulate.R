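test_that("simulation is fully deterministic under a seed", {
  cfg <- sim_config(n_cats = 2, study_days = 6, seed = 7)
  pop1 <- simulate_population(cfg)
  pop2 <- simulate_population(cfg)
  expect_identical(pop1$tracks$cat01$fixes, pop2$tracks$cat01$fixes)
  expect_identical(pop1$truth, pop2$truth)
  # byte-level CSV determinism
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tracks(pop1$tracks, f1)
  write_tracks(pop2$tracks, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("adding cats never perturbs existing cats' data", {
  small <- simulate_population(sim_config(n_cats = 3, study_days = 6, seed = 7))
  large <- simulate_population(sim_config(n_cats = 6, study_days = 6, seed = 7))
  for (id in names(small$tracks))
    expect_identical(small$tracks[[id]]$fixes, large$tracks[[id]]$fixes)
})

test_that("planted EHPE outliers follow the configured binomial rate", {
  cfg <- sim_config(n_cats = 1, study_days = 28, ehpe_outlier_rate = 0.02,
                    missing_day_prob = 0, seed = 5)
  sim <- simulate_cat("c", c(0, 0), cfg, 9001)
  n <- n_fixes(sim$track)
  expect_gt(n, 10000)
  expected <- n * 0.02
  sd3 <- 3 * sqrt(n * 0.02 * 0.98)
  expect_lt(abs(sim$truth$n_ehpe_outliers - expected), sd3)
  # and the EHPE filter removes exactly the planted count
  kept <- filter_ehpe(sim$track)
  expect_equal(n - n_fixes(kept), sim$truth$n_ehpe_outliers)
})

test_that("empirical outdoor hours converge to the configured schedule", {
  cfg <- sim_config(n_cats = 1, study_days = 28, missing_day_prob = 0.15,
                    seed = 3)
  sim <- simulate_cat("c", c(0, 0), cfg, 4321)
  target <- mean(cfg$excursion_hours_per_day_range)
  expect_equal(mean(sim$truth$outdoor_hours), target, tolerance = 0.1)
})

test_that("strong home attraction keeps >= 90% of outdoor fixes near home", {
  cfg <- sim_config(n_cats = 1, study_days = 10, attraction_rate = 0.1,
                    sigma2_m_range = c(10, 10), indoor_bout_fraction = 0,
                    seed = 2)
  sim <- simulate_cat("c", c(500, 500), cfg, 111)
  expect_gte(sim$truth$frac_within_50m, 0.9)
  d <- sqrt((sim$track$fixes$x - 500)^2 + (sim$track$fixes$y - 500)^2)
  expect_gte(mean(d <= 50), 0.9)
})

test_that("generated data satisfy track invariants through the filter chain", {
  pop <- simulate_population(sim_config(n_cats = 3, study_days = 8, seed = 13))
  for (id in names(pop$tracks)) {
    tr <- pop$tracks[[id]]
    tr <- filter_ehpe(filter_download_days(filter_first_days(filter_elevation(tr))))
    ts <- as.numeric(tr$fixes$timestamp)
    expect_true(all(diff(ts) > 0))
    expect_true(all(tr$fixes$elevation >= 0 & tr$fixes$elevation <= 300))
    expect_true(all(tr$fixes$ehpe < 5000))
    expect_true(all(is.finite(tr$fixes$x)), info = id)
    thinned <- thin_track(tr)
    expect_true(all(diff(as.numeric(thinned$fixes$timestamp)) >= 120))
  }
})

test_that("population layout places homes apart and inside the urban polygon", {
  pop <- simulate_population(sim_config(n_cats = 8, study_days = 4, seed = 9))
  pts <- t(vapply(pop$homes, function(h) h$home_point, numeric(2)))
  # two-cat households share a home; distinct homes are well separated
  dists <- as.matrix(dist(unique(pts)))
  diag(dists) <- Inf
  expect_gt(min(dists), 20)
  urban <- pop$landcover$classes$urban[[1]]
  expect_true(all(point_in_polygon(pts[, 1], pts[, 2], urban)))
  # expected stationary intensity integrates to the summed true weights
  grid <- make_grid(pts[, 1], pts[, 2], 10, 400)
  exp_int <- expected_population_intensity(pop, grid)
  w_true <- sum(vapply(pop$truth, function(tr) mean(tr$outdoor_hours / 24),
                       numeric(1)))
  expect_equal(sum(exp_int$values), w_true, tolerance = 0.01)
})
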