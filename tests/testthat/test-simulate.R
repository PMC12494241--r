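test_that("strip layouts assign labels as designed", {
  a <- square_area(120)
  d2i <- trial_design(a, 2, 20, layout = "interleaved")
  expect_identical(as.character(layout_treatments(d2i)),
                   rep(c("T1", "T2"), 3))
  d2c <- trial_design(a, 2, 20, layout = "continuous")
  expect_identical(as.character(layout_treatments(d2c)),
                   c("T1", "T1", "T1", "T2", "T2", "T2"))
  a5 <- study_area(list(rbind(c(0, 0), c(200, 0), c(200, 120), c(0, 120))),
                   crs = 32723)
  d5 <- trial_design(a5, 5, 20, layout = "interleaved")
  expect_identical(as.character(layout_treatments(d5)),
                   rep(sprintf("T%d", 1:5), 2))
  expect_error(trial_design(a, 3, 20, layout = "continuous"),
               class = "geogain_error_unsupported_design")
  expect_error(trial_design(a, 2, 33), class = "geogain_error_config")
})

test_that("harvest tracks hit the closed-form point count and equal quotas", {
  a <- study_area(list(rbind(c(0, 0), c(200, 0), c(200, 120), c(0, 120))),
                  crs = 32723)
  design <- trial_design(a, 2, 20)
  spec <- grid_spec(c(0, 0, 200, 120), 4)
  vm <- variogram_model("spherical", nugget = 1, partial_sill = 100, range_ = 40)
  base <- simulate_gaussian_field(vm, spec, mean = 100, seed = 2, crs = 32723)
  truth <- field_truth(base, c(T1 = 0, T2 = 0), noise_sd = 0)
  s <- sample_harvest_tracks(truth, design, along_spacing = 10,
                             across_spacing = 5, seed = 3)
  # enumeration: 10 strips x floor(20/5)=4 tracks x floor(120/10)=12 points
  expect_identical(nrow(s), 10L * 4L * 12L)
  tab <- table(s$treatment)
  expect_identical(as.integer(tab), rep(240L, 2))   # equal quantities
  # noise-free, zero-effect: samples equal the baseline at their cells
  expect_equal(s$value, sample_raster_at_points(base, s$x, s$y),
               tolerance = 1e-12)
})

test_that("treatment effects shift sampled strips additively", {
  st0 <- simulate_trial(effects = c(T1 = 0, T2 = 0), seed = 5, noise_sd = 0)
  st1 <- simulate_trial(effects = c(T1 = 250, T2 = 0), seed = 5, noise_sd = 0)
  d <- st1$samples$value - st0$samples$value
  expect_true(all(d[st1$samples$treatment == "T1"] == 250))
  expect_true(all(d[st1$samples$treatment == "T2"] == 0))
})

test_that("generator is deterministic in the seed", {
  s1 <- simulate_trial(seed = 12)
  s2 <- simulate_trial(seed = 12)
  expect_identical(s1$samples$value, s2$samples$value)
  expect_identical(s1$truth$baseline$values, s2$truth$baseline$values)
  s3 <- simulate_trial(seed = 13)
  expect_false(identical(s1$samples$value, s3$samples$value))
})

test_that("pure-nugget field is i.i.d. with the requested variance", {
  vm <- variogram_model("exponential", nugget = 1, partial_sill = 0, range_ = 1)
  spec <- grid_spec(c(0, 0, 100, 100), 2)   # 50x50 cells
  g <- simulate_gaussian_field(vm, spec, mean = 0, seed = 8)
  v <- as.vector(g$values)
  expect_equal(var(v), 1, tolerance = 0.15)
  # neighbouring cells are uncorrelated
  expect_lt(abs(cor(v[-1], v[-length(v)])), 0.1)
})

test_that("a zero-variance model cannot be simulated", {
  vm <- variogram_model("spherical", nugget = 0, partial_sill = 0, range_ = 10)
  spec <- grid_spec(c(0, 0, 10, 10), 1)
  expect_error(simulate_gaussian_field(vm, spec, seed = 1),
               class = "geogain_error_degenerate_model")
})

test_that("realised spatial structure matches the generating variogram", {
  vm <- variogram_model("spherical", nugget = 0.1, partial_sill = 1, range_ = 40)
  spec <- grid_spec(c(0, 0, 120, 120), 2)
  hs <- c(5, 15, 25, 35)
  gbar <- rep(0, length(hs))
  for (sd in 1:5) {
    g <- simulate_gaussian_field(vm, spec, mean = 0, seed = sd)
    cc <- expand.grid(y = seq(119, 1, by = -2), x = seq(1, 119, by = 2))
    ev <- empirical_variogram(cc$x, cc$y, as.vector(g$values),
                              n_lags = 12, max_dist = 60)
    gbar <- gbar + approx(ev$lag_center, ev$gamma_hat, xout = hs)$y / 5
  }
  expect_true(all(abs(gbar - model_gamma(vm, hs)) / model_gamma(vm, hs) < 0.25))
})
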