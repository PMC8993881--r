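uniform_catscape <- function(n = 10, cell = 10, total = 1) {
  grid <- grid_spec(0, 0, cell, n, n)
  aggregate_uds(list(ud_raster(grid, matrix(total / n^2, n, n), "u")),
                weights = c(u = total))
}

test_that("intensity fold range is 1 for uniform, max/min otherwise", {
  expect_equal(intensity_fold_range(uniform_catscape()), 1)
  grid <- grid_spec(0, 0, 10, 1, 2)
  cs <- aggregate_uds(list(ud_raster(grid, matrix(c(0.8, 0.2), 2, 1), "u")),
                      weights = c(u = 1))
  expect_equal(intensity_fold_range(cs, level = 1), 4)
})

test_that("fold range on a Gaussian surface matches direct recomputation", {
  ud <- gaussian_ud(sigma = 50, cell = 10, half = 250)
  cs <- aggregate_uds(list(ud), weights = c(gauss = 1))
  fr <- intensity_fold_range(cs, 0.99)
  # independent recomputation: explicit sort-based mass cut, then max/min
  v <- as.vector(ud$values)
  o <- order(v, decreasing = TRUE)
  k <- which(cumsum(v[o]) >= 0.99)[1]
  sel <- v[v >= v[o[k]] & v > 0]
  expect_equal(fr, max(sel) / min(sel), tolerance = 1e-12)
  expect_gt(fr, 1)
})

test_that("near-home ratio is 1 on uniform surfaces and matches a zonal oracle", {
  cs <- uniform_catscape(n = 40, cell = 5)
  expect_equal(near_home_intensity_ratio(cs, matrix(c(100, 100), 1)), 1)
  # Gaussian UD centred at the home
  ud <- gaussian_ud(sigma = 30, cell = 5, half = 150, center = c(0, 0))
  cs2 <- aggregate_uds(list(ud), weights = c(g = 1))
  ratio <- near_home_intensity_ratio(cs2, matrix(c(0, 0), 1), 50, 100)
  # zonal-mean oracle with an explicit double loop
  acc <- c(near = 0, nn = 0, ring = 0, nr = 0)
  cx <- cell_centers_x(ud$grid); cy <- cell_centers_y(ud$grid)
  for (i in seq_along(cy)) for (j in seq_along(cx)) {
    d <- sqrt(cx[j]^2 + cy[i]^2)
    if (d <= 50) { acc["near"] <- acc["near"] + ud$values[i, j]; acc["nn"] <- acc["nn"] + 1 }
    else if (d <= 100) { acc["ring"] <- acc["ring"] + ud$values[i, j]; acc["nr"] <- acc["nr"] + 1 }
  }
  oracle <- (acc[["near"]] / acc[["nn"]]) / (acc[["ring"]] / acc[["nr"]])
  expect_equal(ratio, oracle, tolerance = 1e-12)
  expect_gt(ratio, 1)
})

test_that("near-home ratio is translation-invariant and validates zones", {
  ud <- gaussian_ud(sigma = 30, cell = 5, half = 150, center = c(0, 0))
  cs <- aggregate_uds(list(ud), weights = c(g = 1))
  ud_sh <- gaussian_ud(sigma = 30, cell = 5, half = 150, center = c(500, -300))
  cs_sh <- aggregate_uds(list(ud_sh), weights = c(g = 1))
  expect_equal(near_home_intensity_ratio(cs, matrix(c(0, 0), 1)),
               near_home_intensity_ratio(cs_sh, matrix(c(500, -300), 1)),
               tolerance = 1e-9)
  small <- uniform_catscape(n = 2, cell = 10)
  expect_error(near_home_intensity_ratio(small, matrix(c(1e5, 1e5), 1)),
               "within r1")
})

test_that("distance stats follow the definitions", {
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  tr <- toy_track(30 * (0:19), x = 40 * cos(th), y = 40 * sin(th))
  ds <- distance_stats(tr, c(0, 0))
  expect_equal(ds$frac_within, 1)
  expect_equal(ds$mean_dist_m, 40)
  expect_equal(ds$max_dist_m, 40)
  tr2 <- toy_track(c(0, 30), x = c(10, 110), y = 0)
  ds2 <- distance_stats(tr2, c(0, 0))
  expect_equal(ds2$frac_within, 0.5)
  expect_equal(ds2$mean_dist_m, 60)
  expect_equal(ds2$max_dist_m, 110)
  # translation invariance
  tr3 <- toy_track(c(0, 30), x = c(10, 110) + 77, y = 0 - 31)
  expect_equal(distance_stats(tr3, c(77, -31))[-1], ds2[-1])
  empty <- cat_track("e", data.frame(
    timestamp = as.POSIXct(character(), tz = "UTC"), x = numeric(0),
    y = numeric(0), elevation = numeric(0), ehpe = numeric(0)))
  expect_error(distance_stats(empty, c(0, 0)), "no fixes")
})

test_that("land-cover partition: full urban cover gives (0, 0)", {
  cs <- uniform_catscape(n = 10, cell = 10)
  lc <- landcover(list(urban = list(square_polygon(50, 50, 300))),
                  urban_classes = "urban")
  part <- landcover_partition(cs, lc, level = 1)
  expect_equal(part$fraction_area_outside, 0)
  expect_equal(part$fraction_intensity_outside, 0)
})

test_that("half-plane urban split of a symmetric surface gives ~0.5 each", {
  ud <- gaussian_ud(sigma = 40, cell = 10, half = 200, center = c(0, 0))
  cs <- aggregate_uds(list(ud), weights = c(g = 1))
  west <- cbind(x = c(-1000, 0, 0, -1000), y = c(-1000, -1000, 1000, 1000))
  lc <- landcover(list(urban = list(west)), urban_classes = "urban")
  part <- landcover_partition(cs, lc, level = 0.99)
  expect_equal(part$fraction_area_outside, 0.5, tolerance = 0.02)
  expect_equal(part$fraction_intensity_outside, 0.5, tolerance = 0.02)
})

test_that("checkerboard partition matches a hand tally", {
  grid <- grid_spec(0, 0, 10, 2, 2)
  vals <- matrix(c(0.4, 0.3, 0.2, 0.1), 2, 2)  # col-major
  cs <- aggregate_uds(list(ud_raster(grid, vals, "u")), weights = c(u = 1))
  # urban covers only the west column of cell centers (x = 5, not x = 15)
  west_col <- cbind(x = c(-5, 12, 12, -5), y = c(-5, -5, 25, 25))
  lc <- landcover(list(urban = list(west_col)), urban_classes = "urban")
  part <- landcover_partition(cs, lc, level = 1)
  expect_equal(part$fraction_area_outside, 0.5)
  expect_equal(part$fraction_intensity_outside, 0.2 + 0.1)
})
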