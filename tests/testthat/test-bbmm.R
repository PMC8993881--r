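test_that("identical positions give zero motion variance", {
  tr <- toy_track(120 * (0:9), x = rep(5, 10), y = rep(5, 10))
  mv <- estimate_motion_variance(tr, location_error = 5)
  expect_s3_class(mv, "motion_variance")
  expect_equal(mv$sigma2_m, 0)
})

test_that("optimizer matches a dense grid search of the same likelihood", {
  set.seed(21)
  s2_true <- 25 / 60
  n <- 400
  xs <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s2_true * 120))))
  ys <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s2_true * 120))))
  tr <- toy_track(120 * (0:(n - 1)),
                  x = xs + rnorm(n, 0, 5), y = ys + rnorm(n, 0, 5))
  mv <- estimate_motion_variance(tr, location_error = 5)
  # independent oracle: 1001-point grid over the same bracket
  dt <- diff(as.numeric(tr$fixes$timestamp))
  sigma_max <- max((diff(tr$fixes$x)^2 + diff(tr$fixes$y)^2) / dt)
  grid <- seq(0, sigma_max, length.out = 1001)
  nlls <- vapply(grid, function(s2) loo_nll_oracle(tr, s2, 5), numeric(1))
  expect_lt(abs(mv$sigma2_m - grid[which.min(nlls)]), grid[2] - grid[1])
  expect_equal(mv$loglik, -min(nlls), tolerance = 1e-6)
})

test_that("triplets crossing gaps longer than max_lag are excluded", {
  # a huge displacement hidden behind an overnight gap must not inflate sigma2
  ts <- c(0, 120, 240, 360, 50000, 50120, 50240)
  x <- c(0, 1, 0, 1, 5000, 5001, 5000)
  tr <- toy_track(ts, x = x, y = 0)
  mv <- estimate_motion_variance(tr, location_error = 5, max_lag = 3600)
  expect_equal(mv$n_triplets, 2)    # fixes 2 and 6 usable only
  expect_lt(mv$sigma2_m * 60, 1)
  tiny <- toy_track(c(0, 50000, 100000), x = c(0, 1, 0), y = 0)
  expect_error(estimate_motion_variance(tiny, 5), "triplet")
})

test_that("UD mass is conserved across grid resolutions", {
  set.seed(5)
  xs <- cumsum(rnorm(40, 0, 10)); ys <- cumsum(rnorm(40, 0, 10))
  tr <- toy_track(120 * (0:39), x = xs, y = ys)
  mv <- estimate_motion_variance(tr, 5)
  for (cell in c(5, 10)) {
    grid <- make_grid(xs, ys, cell_size = cell, buffer = 150)
    ud <- compute_ud(tr, mv, 5, grid)
    expect_equal(sum(ud$values), 1, tolerance = 1e-6)
    expect_true(all(ud$values >= 0))
  }
})

test_that("UD is translation-equivariant and mirror-symmetric", {
  tr <- toy_track(c(0, 120, 240), x = c(-30, 0, 30), y = c(0, 10, 0))
  grid <- grid_spec(-100, -100, 10, 20, 20)
  ud <- compute_ud(tr, 25 / 60, 5, grid)
  # translation by one grid-aligned offset
  tr2 <- toy_track(c(0, 120, 240), x = c(-30, 0, 30) + 40, y = c(0, 10, 0) - 20)
  grid2 <- grid_spec(-100 + 40, -100 - 20, 10, 20, 20)
  ud2 <- compute_ud(tr2, 25 / 60, 5, grid2)
  expect_equal(ud2$values, ud$values, tolerance = 1e-12)
  # mirror x -> -x about the grid center (x = 0)
  tr3 <- toy_track(c(0, 120, 240), x = -c(-30, 0, 30), y = c(0, 10, 0))
  ud3 <- compute_ud(tr3, 25 / 60, 5, grid)
  expect_equal(ud3$values, ud$values[, ncol(ud$values):1], tolerance = 1e-9)
})

test_that("larger motion variance never shrinks the 95% home range", {
  tr <- toy_track(120 * (0:9), x = 10 * (0:9), y = c(0, 15, 0, 15, 0, 15, 0, 15, 0, 15))
  grid <- make_grid(tr$fixes$x, tr$fixes$y, 10, 300)
  areas <- vapply(c(5, 25, 100) / 60, function(s2) {
    volume_contour(compute_ud(tr, s2, 5, grid), 0.95)$area_ha
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("compute_ud errors when no pair fits within max_lag", {
  tr <- toy_track(c(0, 50000), x = c(0, 10), y = 0)
  grid <- grid_spec(-100, -100, 10, 20, 20)
  expect_error(compute_ud(tr, 25 / 60, 5, grid), "max_lag")
})
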