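test_that("alignment is the identity on matching grids", {
  ud <- gaussian_ud(sigma = 30, cell = 10, half = 100)
  out <- align_rasters(list(ud), ud$grid)[[1]]
  expect_identical(out$values, ud$values)
})

test_that("conservative resampling preserves mass across resolutions", {
  ud <- gaussian_ud(sigma = 30, cell = 5, half = 100)
  template <- grid_spec(-100, -100, 10, 20, 20)
  out <- align_rasters(list(ud), template)[[1]]
  expect_equal(sum(out$values), sum(ud$values), tolerance = 1e-6)
  # and each coarse cell is the sum of its four fine cells
  expect_equal(out$values[1, 1], sum(ud$values[1:2, 1:2]))
})

test_that("a unit-mass cell splits across template cells by overlap area", {
  src <- ud_raster(grid_spec(3, 4, 10, 1, 1), matrix(1, 1, 1))
  template <- grid_spec(0, 0, 10, 2, 2)
  out <- align_rasters(list(src), template)[[1]]
  # source square [3,13]x[4,14]: x overlaps 0.7/0.3, y overlaps 0.6/0.4
  expect_equal(out$values,
               matrix(c(0.4 * 0.7, 0.6 * 0.7, 0.4 * 0.3, 0.6 * 0.3), 2, 2),
               tolerance = 1e-12)
})

test_that("alignment rejects disjoint and non-covering templates", {
  src <- ud_raster(grid_spec(0, 0, 10, 4, 4), matrix(1 / 16, 4, 4))
  expect_error(align_rasters(list(src), grid_spec(1000, 1000, 10, 4, 4)),
               "disjoint")
  expect_error(align_rasters(list(src), grid_spec(0, 0, 10, 2, 2)),
               "cover")
})

test_that("weighting rescales a unit UD to w and validates inputs", {
  ud <- gaussian_ud(sigma = 30, cell = 10, half = 100)
  expect_identical(weight_ud(ud, 1)$values, ud$values)
  expect_equal(sum(weight_ud(ud, 0.35)$values), 0.35, tolerance = 1e-9)
  expect_true(all(weight_ud(ud, 0)$values == 0))
  expect_error(weight_ud(ud, 1.2), "\\[0, 1\\]")
  expect_error(weight_ud(weight_ud(ud, 0.5), 0.5), "sum to 1")
})

test_that("aggregation is linear, order-invariant and conserves weight", {
  ud <- gaussian_ud(sigma = 30, cell = 10, half = 100)
  ud2 <- gaussian_ud(sigma = 50, center = c(20, -10), grid = ud$grid)
  w <- c(a = 0.3, b = 0.2)
  cs <- aggregate_uds(list(weight_ud(ud, w["a"]), weight_ud(ud2, w["b"])))
  expect_equal(sum(cs$raster$values), sum(w), tolerance = 1e-9)
  # two identical UDs with w 0.3 and 0.2 equal 0.5 x the UD
  cs_same <- aggregate_uds(list(weight_ud(ud, 0.3), weight_ud(ud, 0.2)))
  expect_equal(cs_same$raster$values, 0.5 * ud$values, tolerance = 1e-12)
  # order invariance
  cs_rev <- aggregate_uds(list(weight_ud(ud2, w["b"]), weight_ud(ud, w["a"])))
  expect_equal(cs$raster$values, cs_rev$raster$values)
  # single cat with w = 1 reproduces its UD
  expect_equal(aggregate_uds(list(weight_ud(ud, 1)))$raster$values, ud$values)
})

test_that("doubling weights doubles cells; dropping a cat never adds mass", {
  ud <- gaussian_ud(sigma = 30, cell = 10, half = 100)
  ud2 <- gaussian_ud(sigma = 50, center = c(20, -10), grid = ud$grid)
  cs1 <- aggregate_uds(list(weight_ud(ud, 0.2), weight_ud(ud2, 0.3)))
  cs2 <- aggregate_uds(list(weight_ud(ud, 0.4), weight_ud(ud2, 0.6)))
  expect_equal(cs2$raster$values, 2 * cs1$raster$values, tolerance = 1e-12)
  cs_drop <- aggregate_uds(list(weight_ud(ud, 0.2)))
  expect_true(all(cs_drop$raster$values <= cs1$raster$values + 1e-15))
})

test_that("aggregation refuses mismatched grids", {
  ud <- gaussian_ud(sigma = 30, cell = 10, half = 100)
  ud_off <- gaussian_ud(sigma = 30, cell = 10, half = 110)
  expect_error(aggregate_uds(list(weight_ud(ud, 0.5), weight_ud(ud_off, 0.5))),
               "common grid")
})
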