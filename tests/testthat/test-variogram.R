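test_that("Matheron estimator matches hand and loop computations", {
  # two points 10 m apart, values 0 and 2, one effective bin: (2-0)^2 / 2
  ev <- empirical_variogram(c(0, 10), c(0, 0), c(0, 2), n_lags = 3, max_dist = 30)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gamma_hat, 2)
  expect_equal(ev$pair_count, 1L)

  # random cloud versus an explicit pair-loop reference, bin by bin
  set.seed(21)
  x <- runif(40, 0, 100); y <- runif(40, 0, 100); v <- rnorm(40)
  ev2 <- empirical_variogram(x, y, v, n_lags = 10, max_dist = 150)
  width <- 15
  for (k in seq_len(nrow(ev2))) {
    lo <- ev2$lag_center[k] - width / 2; hi <- ev2$lag_center[k] + width / 2
    expect_equal(ev2$gamma_hat[k], matheron_loop(x, y, v, lo, hi),
                 tolerance = 1e-12)
  }

  # constant field -> zero semivariance everywhere
  ev3 <- empirical_variogram(x, y, rep(7, 40), n_lags = 10, max_dist = 150)
  expect_true(all(ev3$gamma_hat == 0))
})

test_that("degenerate inputs are rejected", {
  expect_error(empirical_variogram(5, 5, 1, n_lags = 5, max_dist = 10),
               class = "geogain_error_degenerate_geometry")
  expect_error(empirical_variogram(rep(1, 4), rep(2, 4), 1:4,
                                   n_lags = 5, max_dist = 10),
               class = "geogain_error_degenerate_geometry")
  # a sparse variogram is representable, but unusable for fitting
  ev1 <- empirical_variogram(c(0, 1), c(0, 0), c(0, 1),
                             n_lags = 10, max_dist = 100)
  expect_identical(nrow(ev1), 1L)
  expect_error(fit_variogram(ev1, "spherical"),
               class = "geogain_error_insufficient_structure")
})

test_that("model families evaluate to their closed forms", {
  sph <- variogram_model("spherical", nugget = 0, partial_sill = 1, range_ = 50)
  expect_equal(model_gamma(sph, 50), 1)                      # sill at range
  expect_equal(model_gamma(sph, 25), 0.6875)                 # 1.5*.5 - .5*.5^3
  expect_equal(model_gamma(sph, 120), 1)                     # flat beyond range
  lin <- variogram_model("linear", nugget = 0.5, slope = 0.01)
  expect_equal(model_gamma(lin, 200), 2.5)
  expg <- variogram_model("exponential", nugget = 0.2, partial_sill = 2, range_ = 60)
  expect_equal(model_gamma(expg, 60), 0.2 + 2 * (1 - exp(-3)))
  gau <- variogram_model("gaussian", nugget = 0, partial_sill = 3, range_ = 80)
  expect_equal(model_gamma(gau, 40), 3 * (1 - exp(-3 * 40^2 / 80^2)))
  # gamma(0) = 0 for every family, including with a nugget
  for (m in list(sph, lin, expg, gau)) expect_identical(model_gamma(m, 0), 0)
  expect_error(model_gamma(sph, -1), class = "geogain_error_config")
})

test_that("families are monotone in h and spherical is continuous at the range", {
  h <- seq(0.001, 300, length.out = 400)
  models <- list(
    variogram_model("linear", nugget = 0.1, slope = 0.02),
    variogram_model("exponential", nugget = 0.1, partial_sill = 2, range_ = 70),
    variogram_model("gaussian", nugget = 0.3, partial_sill = 1.5, range_ = 90),
    variogram_model("spherical", nugget = 0.2, partial_sill = 2.5, range_ = 120))
  for (m in models) expect_true(all(diff(model_gamma(m, h)) >= -1e-12))
  sph <- models[[4]]
  expect_lt(abs(model_gamma(sph, 120 - 1e-9) - model_gamma(sph, 120 + 1e-9)),
            1e-11)
})

test_that("noise-free inverse fit recovers generating parameters to 1e-4", {
  for (fam in c("exponential", "gaussian", "spherical")) {
    true <- variogram_model(fam, nugget = 0.1, partial_sill = 2.0, range_ = 100)
    h <- seq(5, 245, length.out = 20)
    ev <- structure(
      data.frame(lag_center = h, gamma_hat = model_gamma(true, h),
                 pair_count = rep(25L, 20)),
      max_dist = 250, class = c("empirical_variogram", "data.frame"))
    fit <- fit_variogram(ev, fam)
    expect_equal(fit$nugget, 0.1, tolerance = 1e-4)
    expect_equal(fit$partial_sill, 2.0, tolerance = 1e-4)
    expect_equal(fit$range_, 100, tolerance = 1e-4)
  }
  lin_true <- variogram_model("linear", nugget = 0.4, slope = 0.03)
  h <- seq(10, 200, by = 10)
  evl <- structure(
    data.frame(lag_center = h, gamma_hat = model_gamma(lin_true, h),
               pair_count = rep(10L, length(h))),
    max_dist = 200, class = c("empirical_variogram", "data.frame"))
  fl <- fit_variogram(evl, "linear")
  expect_equal(fl$nugget, 0.4, tolerance = 1e-8)
  expect_equal(fl$slope, 0.03, tolerance = 1e-8)
})

test_that("pure-nugget data fit as nugget, not structure", {
  set.seed(5)
  x <- runif(300, 0, 100); y <- runif(300, 0, 100); v <- rnorm(300, 0, 1)
  ev <- empirical_variogram(x, y, v, n_lags = 15, max_dist = 80)
  fit <- fit_variogram(ev, "spherical")
  expect_equal(fit$nugget, 1, tolerance = 0.1)
  expect_lt(fit$partial_sill, 0.1 * fit$nugget)
  expect_error(fit_variogram(ev[1:2, ], "spherical"),
               class = "geogain_error_insufficient_structure")
})

test_that("fitting is scale-equivariant in the variable", {
  set.seed(9)
  x <- runif(200, 0, 200); y <- runif(200, 0, 200)
  true <- variogram_model("spherical", nugget = 0.2, partial_sill = 1, range_ = 60)
  spec <- grid_spec(c(0, 0, 200, 200), 4)
  g <- simulate_gaussian_field(true, spec, seed = 31)
  v <- sample_raster_at_points(g, x, y)
  fit1 <- fit_variogram(empirical_variogram(x, y, v, 20, 150), "spherical")
  fit2 <- fit_variogram(empirical_variogram(x, y, 10 * v, 20, 150), "spherical")
  expect_equal(fit2$nugget, 100 * fit1$nugget, tolerance = 1e-3)
  expect_equal(fit2$partial_sill, 100 * fit1$partial_sill, tolerance = 1e-3)
  expect_equal(fit2$range_, fit1$range_, tolerance = 1e-3)
})
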