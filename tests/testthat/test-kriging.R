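nb_all <- neighborhood_config(min_neighbors = 1, max_neighbors = 1000)

test_that("constant training data force a constant estimate anywhere", {
  vm <- variogram_model("spherical", nugget = 0.1, partial_sill = 1, range_ = 50)
  set.seed(2); x <- runif(30, 0, 100); y <- runif(30, 0, 100)
  for (tg in list(c(50, 50), c(-20, 130), c(0, 0)))
    expect_equal(krige_point(x, y, rep(7, 30), vm, tg, nb_all)$estimate, 7,
                 tolerance = 1e-10)
})

test_that("ordinary kriging is exact at a training location", {
  vm <- variogram_model("spherical", nugget = 0, partial_sill = 2, range_ = 40)
  set.seed(3); x <- runif(25, 0, 100); y <- runif(25, 0, 100); z <- rnorm(25, 10)
  r <- krige_point(x, y, z, vm, c(x[7], y[7]), nb_all)
  expect_equal(r$estimate, z[7], tolerance = 1e-8)
  # exactness survives a fitted nugget because gamma(0) = 0 by convention
  vm2 <- variogram_model("exponential", nugget = 0.5, partial_sill = 2, range_ = 40)
  r2 <- krige_point(x, y, z, vm2, c(x[12], y[12]), nb_all)
  expect_equal(r2$estimate, z[12], tolerance = 1e-8)
})

test_that("kriging agrees with the dense-solve oracle on small configurations", {
  vm <- variogram_model("spherical", nugget = 0, partial_sill = 1, range_ = 50)
  # minimal hand-checkable 3-point configuration
  o <- ok_oracle(c(0, 10, 0), c(0, 0, 10), c(1, 2, 3), vm, 5, 5)
  r <- krige_point(c(0, 10, 0), c(0, 0, 10), c(1, 2, 3), vm, c(5, 5),
                   neighborhood_config(min_neighbors = 1))
  expect_equal(r$estimate, o$estimate, tolerance = 1e-10)
  expect_equal(r$variance, o$variance, tolerance = 1e-10)

  # random <= 50-point clouds, all four families, random targets
  set.seed(14)
  for (fam in c("linear", "exponential", "gaussian", "spherical")) {
    n <- sample(10:50, 1)
    x <- runif(n, 0, 200); y <- runif(n, 0, 200); z <- rnorm(n, 50, 5)
    vm <- if (fam == "linear")
      variogram_model("linear", nugget = 0.2, slope = 0.01)
    else variogram_model(fam, nugget = 0.2, partial_sill = 1.5, range_ = 70)
    for (k in 1:3) {
      tg <- runif(2, 0, 200)
      o <- ok_oracle(x, y, z, vm, tg[1], tg[2])
      r <- krige_point(x, y, z, vm, tg, nb_all)
      expect_equal(r$estimate, o$estimate, tolerance = 1e-10)
      expect_equal(sum(r$weights), 1, tolerance = 1e-8)
    }
  }
})

test_that("grid kriging matches per-point kriging cell by cell", {
  vm <- variogram_model("spherical", nugget = 0, partial_sill = 1, range_ = 50)
  x <- c(0, 10, 0); y <- c(0, 0, 10); z <- c(1, 2, 3)
  spec <- grid_spec(c(0, 0, 20, 20), 1)
  g <- krige_grid(x, y, z, vm, spec, neighborhood_config(min_neighbors = 1),
                  crs = 32723)
  cc <- expand.grid(i = 1:20, j = 1:20)
  for (k in sample(nrow(cc), 25)) {
    tx <- 0 + (cc$j[k] - 0.5); ty <- 20 - (cc$i[k] - 0.5)
    o <- ok_oracle(x, y, z, vm, tx, ty)
    expect_equal(g$values[cc$i[k], cc$j[k]], o$estimate, tolerance = 1e-10)
  }
  ws <- attr(g, "weight_sums")
  expect_lt(max(abs(ws - 1)), 1e-8)
  expect_true(all(attr(g, "variance") >= -1e-10))
})

test_that("local mode equals global mode when the neighbourhood covers everything", {
  set.seed(8)
  x <- runif(40, 0, 100); y <- runif(40, 0, 100); z <- rnorm(40, 20)
  vm <- variogram_model("exponential", nugget = 0.1, partial_sill = 1, range_ = 30)
  spec <- grid_spec(c(0, 0, 100, 100), 10)
  gg <- krige_grid(x, y, z, vm, spec,
                   neighborhood_config("global", min_neighbors = 1,
                                       max_neighbors = 40), crs = 0)
  gl <- krige_grid(x, y, z, vm, spec,
                   neighborhood_config("local", max_search_distance = 1000,
                                       min_neighbors = 1, max_neighbors = 40),
                   crs = 0)
  expect_identical(gg$values, gl$values)
})

test_that("estimates are translation invariant", {
  set.seed(4)
  x <- runif(30, 0, 100); y <- runif(30, 0, 100); z <- rnorm(30, 5)
  vm <- variogram_model("spherical", nugget = 0.05, partial_sill = 1, range_ = 60)
  r1 <- krige_point(x, y, z, vm, c(40, 60), nb_all)
  r2 <- krige_point(x + 1e5, y - 2e5, z, vm, c(40 + 1e5, 60 - 2e5), nb_all)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-9)
})

test_that("neighbourhood limits behave: caps, empty search, warnings", {
  set.seed(6)
  x <- runif(30, 0, 100); y <- runif(30, 0, 100); z <- rnorm(30)
  vm <- variogram_model("spherical", nugget = 0.1, partial_sill = 1, range_ = 50)
  r <- krige_point(x, y, z, vm, c(50, 50),
                   neighborhood_config(max_neighbors = 20))
  expect_length(r$weights, 20L)
  # local search with nothing in range -> masked, not an error
  rf <- krige_point(x, y, z, vm, c(1e6, 1e6),
                    neighborhood_config("local", max_search_distance = 10,
                                        min_neighbors = 1))
  expect_true(is.na(rf$estimate))
  # fewer than min_neighbors available -> all used, with a warning
  expect_warning(
    r2 <- krige_point(x[1:5], y[1:5], z[1:5], vm, c(50, 50),
                      neighborhood_config(min_neighbors = 16)),
    class = "geogain_warning_few_neighbors")
  expect_length(r2$weights, 5L)
  expect_error(krige_point(1, 1, 5, vm, c(0, 0)),
               class = "geogain_error_degenerate_geometry")
})
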