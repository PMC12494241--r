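test_that("point sampling uses containing-cell lookup with half-open cells", {
  g <- tiny_grid()   # 3x4, pixel 1, origin (0, 3), value NA at [2, 3]
  # cell centres
  expect_equal(sample_raster_at_points(g, 0.5, 2.5), g$values[1, 1])
  expect_equal(sample_raster_at_points(g, 3.5, 0.5), g$values[3, 4])
  # 1 cm inside a boundary still belongs to the containing cell
  expect_equal(sample_raster_at_points(g, 1.01, 2.99), g$values[1, 2])
  expect_equal(sample_raster_at_points(g, 0.99, 2.99), g$values[1, 1])
  # x boundary belongs to the cell on its right (x in [x0, x0 + p))
  expect_equal(sample_raster_at_points(g, 1, 2.5), g$values[1, 2])
  # outside and nodata are NA
  expect_true(is.na(sample_raster_at_points(g, -0.1, 1)))
  expect_true(is.na(sample_raster_at_points(g, 2.5, 1.5)))  # the masked cell
  # CRS mismatch between a sample_set and grid is an error
  s <- tiny_samples(crs = 32633)
  expect_error(sample_raster_at_points(g, s), class = "geogain_error_crs")
})

test_that("clipping masks by cell-centre containment and is idempotent", {
  v <- matrix(as.numeric(1:16), 4, 4)
  g <- raster_grid(v, 0, 4, 1, 32723)
  sq <- study_area(list(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))), crs = 32723)
  cl <- clip_to_area(g, sq)
  expect_identical(sum(!is.na(cl$values)), 4L)   # centres (0.5,1.5)x(0.5,1.5)
  expect_identical(cl$values[3:4, 1:2], v[3:4, 1:2])
  expect_identical(dim(cl$values), dim(v))
  # idempotence
  expect_identical(clip_to_area(cl, sq)$values, cl$values)
  # full cover leaves the grid untouched
  big <- study_area(list(rbind(c(-1, -1), c(5, -1), c(5, 5), c(-1, 5))),
                    crs = 32723)
  expect_identical(clip_to_area(g, big)$values, v)
  # disjoint polygon: all masked plus a warning
  far <- study_area(list(rbind(c(100, 100), c(101, 100), c(101, 101), c(100, 101))),
                    crs = 32723)
  expect_warning(cf <- clip_to_area(g, far), class = "geogain_warning_empty_clip")
  expect_true(all(is.na(cf$values)))
})

test_that("polygon holes are excluded from containment", {
  outer <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  hole <- rbind(c(4, 4), c(6, 4), c(6, 6), c(4, 6))
  a <- study_area(list(list(outer, hole)), crs = 32723)
  expect_equal(area_of(a), 96)
  expect_false(points_in_area(a, 5, 5))
  expect_true(points_in_area(a, 2, 2))
})

test_that("gain surfaces subtract cellwise, propagate masks, antisymmetric", {
  a <- raster_grid(matrix(c(5, 6, NA, 8), 2, 2), 0, 2, 1, 32723)
  b <- raster_grid(matrix(c(1, NA, 3, 4), 2, 2), 0, 2, 1, 32723)
  gain <- gain_surface(a, b)
  expect_equal(gain$values, matrix(c(4, NA, NA, 4), 2, 2))
  rev <- gain_surface(b, a)
  expect_equal(rev$values, -gain$values)
  expect_equal(gain_surface(a, a)$values, matrix(c(0, 0, NA, 0), 2, 2))
  # constant offset
  b2 <- a; b2$values <- a$values - 300
  expect_true(all(gain_surface(a, b2)$values == 300, na.rm = TRUE))
  # mismatched grids refuse
  c_ <- raster_grid(matrix(1, 2, 2), 0, 2, 2, 32723)
  expect_error(gain_surface(a, c_), class = "geogain_error_grid_mismatch")
})

test_that("raster statistics use valid cells and the population std", {
  g <- raster_grid(matrix(c(1, 2, 3, NA), 2, 2), 0, 2, 1, 32723)
  st <- raster_stats(g)
  expect_equal(st$minimum, 1)
  expect_equal(st$maximum, 3)
  expect_equal(st$sum, 6)
  expect_equal(st$mean, 2)
  expect_equal(st$std, sqrt(2 / 3))   # divisor n = 3
  expect_identical(st$n_valid, 3L)
  expect_equal(st$mean, st$sum / st$n_valid, tolerance = 1e-9)
  # constant and single-cell degenerate cases
  gc <- raster_grid(matrix(4.5, 3, 3), 0, 3, 1, 0)
  stc <- raster_stats(gc)
  expect_equal(c(stc$minimum, stc$maximum, stc$mean), rep(4.5, 3))
  expect_equal(stc$std, 0)
  expect_equal(stc$sum, 4.5 * 9)
  g1 <- raster_grid(matrix(c(5, NA, NA, NA), 2, 2), 0, 2, 1, 0)
  st1 <- raster_stats(g1)
  expect_equal(st1$mean, 5)
  expect_equal(st1$std, 0)
})
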