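#' Strip-trial design
#'
#' A rectangular field divided into parallel strips of machine width, each
#' strip carrying one treatment. The `interleaved` layout cycles T1..Tk
#' across strips (the usual on-farm design); `continuous` puts the first
#' half of the strips under T1 and the second under T2 and is defined for
#' two treatments only.
#'
#' @param area a [study_area()] whose bounds define the rectangle; strips
#'   tile its envelope.
#' @param n_treatments 2 to 5.
#' @param strip_width strip (machine) width, m; must tile the field span.
#' @param layout `"interleaved"` or `"continuous"`.
#' @param orientation `"columns"` (strips are vertical bands indexed along
#'   x; harvester tracks run along y) or `"rows"`.
#' @return list of class `trial_design`.
#' @export
trial_design <- function(area, n_treatments = 2L, strip_width = 20,
                         layout = c("interleaved", "continuous"),
                         orientation = c("columns", "rows")) {
  layout <- match.arg(layout)
  orientation <- match.arg(orientation)
  n_treatments <- as.integer(n_treatments)
  if (n_treatments < 2L || n_treatments > 5L)
    gg_stop("config", "n_treatments must be 2..5")
  if (layout == "continuous" && n_treatments > 2L)
    gg_stop("unsupported_design", "continuous layout is defined for 2 treatments only")
  stopifnot_scalar_number(strip_width, "strip_width", positive = TRUE)
  b <- area_bounds(area)
  span <- if (orientation == "columns") b["xmax"] - b["xmin"] else b["ymax"] - b["ymin"]
  n_strips <- as.integer(round(span / strip_width))
  if (n_strips < n_treatments || abs(n_strips * strip_width - span) > 1e-6)
    gg_stop("config", "strip_width %g does not tile the %g m span", strip_width, span)
  structure(list(area = area, n_treatments = n_treatments,
                 strip_width = strip_width, layout = layout,
                 orientation = orientation, n_strips = n_strips,
                 bounds = b),
            class = "trial_design")
}

#' Treatment label of each strip
#'
#' @param design a [trial_design()].
#' @return character vector, one label (`"T1"`..`"Tk"`) per strip, plus a
#'   `strips` attribute: a data frame with each strip's lower and upper
#'   bound along the strip axis.
#' @examples
#' a <- study_area(list(rbind(c(0, 0), c(120, 0), c(120, 120), c(0, 120))),
#'                 crs = 32723)
#' layout_treatments(trial_design(a, 2, 20))
#' @export
layout_treatments <- function(design) {
  k <- design$n_treatments; ns <- design$n_strips
  labels <- if (design$layout == "interleaved") {
    sprintf("T%d", ((seq_len(ns) - 1L) %% k) + 1L)
  } else {
    c(rep("T1", ceiling(ns / 2)), rep("T2", floor(ns / 2)))
  }
  lo0 <- if (design$orientation == "columns") design$bounds["xmin"] else design$bounds["ymin"]
  strips <- data.frame(lower = lo0 + (seq_len(ns) - 1) * design$strip_width,
                       upper = lo0 + seq_len(ns) * design$strip_width)
  attr(labels, "strips") <- strips
  labels
}

#' Simulate a Gaussian random field on a grid
#'
#' Draws one realisation of a stationary Gaussian field on the cell
#' centres, with covariance `C(h) = sill_total - gamma(h)` derived from the
#' semivariogram (for the linear family, which has no finite sill, a large
#' pseudo-sill of `nugget + slope * d_max` over the grid diagonal `d_max`
#' is used). Exact simulation by Cholesky factorisation of the dense
#' covariance (with 1e-8 relative diagonal jitter), so grids are limited to
#' ~10^4 cells.
#'
#' @param vm a [variogram_model()] with positive total variance.
#' @param spec a [grid_spec()].
#' @param mean field mean added to the zero-mean draw.
#' @param seed integer seed; the draw is reproducible and the global RNG
#'   state is untouched.
#' @param crs CRS identifier stamped on the output.
#' @return a [raster_grid()].
#' @export
simulate_gaussian_field <- function(vm, spec, mean = 0, seed = 1L, crs = 0L) {
  ncell <- spec$nrows * spec$ncols
  if (ncell > 12000L)
    gg_stop("config", "grid of %d cells too large for exact covariance factorisation (max ~10^4)",
            ncell)
  cc <- grid_centers(spec)
  d <- as.matrix(stats::dist(cbind(cc$x, cc$y)))
  sill <- if (vm$family == "linear") vm$nugget + vm$slope * max(d) else total_sill(vm)
  if (sill <= 0)
    gg_stop("degenerate_model", "variogram has zero total variance; nothing to simulate")
  C <- sill - matrix(model_gamma(vm, as.vector(d)), ncell, ncell)
  diag(C) <- diag(C) + 1e-8 * sill
  L <- tryCatch(chol(C), error = function(e)
    gg_stop("generation",
            "covariance not positive definite even after jitter; increase the nugget"))
  zvec <- withr::with_seed(as.integer(seed), stats::rnorm(ncell))
  vals <- mean + as.vector(crossprod(L, zvec))
  raster_grid(matrix(vals, spec$nrows, spec$ncols),
              spec$origin_x, spec$origin_y, spec$pixel, crs)
}

#' Ground truth of a simulated trial
#'
#' @param baseline a [raster_grid()] latent field (kg/ha).
#' @param effects named numeric vector of additive treatment offsets
#'   (kg/ha), one per label `"T1"`..`"Tk"`.
#' @param noise_sd measurement-noise standard deviation (kg/ha), `>= 0`.
#' @param variogram the [variogram_model()] that generated `baseline`.
#' @return list of class `field_truth`.
#' @export
field_truth <- function(baseline, effects, noise_sd = 0, variogram = NULL) {
  if (is.null(names(effects)) || any(!nzchar(names(effects))))
    gg_stop("config", "effects must be a named vector (T1..Tk)")
  if (noise_sd < 0) gg_stop("config", "noise_sd must be >= 0")
  structure(list(baseline = baseline, effects = effects,
                 noise_sd = noise_sd, variogram = variogram),
            class = "field_truth")
}

#' Sample harvester tracks over a simulated trial
#'
#' Places points on parallel tracks within each strip — tracks
#' `across_spacing` apart (offset half a spacing from the strip edge),
#' points every `along_spacing` along the track — and assigns
#' `value = baseline(cell of point) + effect(treatment of strip) + N(0, noise_sd)`.
#' With equal strip counts per treatment the per-treatment sample counts
#' are equal, emulating a harvester covering the trial homogeneously.
#'
#' @param truth a [field_truth()].
#' @param design a [trial_design()] on the same field.
#' @param along_spacing point spacing along a track, m. Default 3.
#' @param across_spacing track spacing, m. Default 5.
#' @param seed integer seed for the measurement noise (and dropout).
#' @param dropout fraction of points dropped at random per track (emulates
#'   gaps in the planting lines). Default 0.
#' @return a [sample_set()] labelled by strip treatment.
#' @export
sample_harvest_tracks <- function(truth, design, along_spacing = 3,
                                  across_spacing = 5, seed = 1L, dropout = 0) {
  stopifnot_scalar_number(along_spacing, "along_spacing", positive = TRUE)
  stopifnot_scalar_number(across_spacing, "across_spacing", positive = TRUE)
  if (across_spacing > design$strip_width)
    gg_stop("config", "across_spacing exceeds the strip width")
  b <- design$bounds
  labels <- layout_treatments(design)
  strips <- attr(labels, "strips")
  along_lo <- if (design$orientation == "columns") b["ymin"] else b["xmin"]
  along_hi <- if (design$orientation == "columns") b["ymax"] else b["xmax"]
  along <- seq(along_lo + along_spacing / 2, along_hi - 1e-9, by = along_spacing)
  if (length(along) == 0L)
    gg_stop("design", "along_spacing %g m yields no points on a track", along_spacing)
  xs <- c(); ys <- c(); trt <- c()
  for (si in seq_len(design$n_strips)) {
    across <- seq(strips$lower[si] + across_spacing / 2,
                  strips$upper[si] - 1e-9, by = across_spacing)
    if (length(across) == 0L)
      gg_stop("design", "across_spacing %g m yields no tracks in a %g m strip",
              across_spacing, design$strip_width)
    if (design$orientation == "columns") {
      xs <- c(xs, rep(across, each = length(along)))
      ys <- c(ys, rep(along, times = length(across)))
    } else {
      ys <- c(ys, rep(across, each = length(along)))
      xs <- c(xs, rep(along, times = length(across)))
    }
    trt <- c(trt, rep(labels[si], length(along) * length(across)))
  }
  base_val <- sample_raster_at_points(truth$baseline, xs, ys)
  if (anyNA(base_val))
    gg_stop("design", "%d track point(s) fall outside the baseline grid",
            sum(is.na(base_val)))
  eff <- truth$effects[trt]
  if (anyNA(eff))
    gg_stop("config", "effects vector lacks entries for: %s",
            paste(setdiff(unique(trt), names(truth$effects)), collapse = ", "))
  n <- length(xs)
  noise <- if (truth$noise_sd > 0)
    withr::with_seed(as.integer(seed), stats::rnorm(n, 0, truth$noise_sd))
  else rep(0, n)
  keep <- if (dropout > 0)
    withr::with_seed(as.integer(seed) + 1L, stats::runif(n) >= dropout)
  else rep(TRUE, n)
  sample_set(xs[keep], ys[keep], (base_val + as.numeric(eff) + noise)[keep],
             trt[keep], crs = truth$baseline$crs,
             variable_name = "yield")
}

#' Simulate a complete strip trial
#'
#' Convenience wrapper producing the study area, ground truth and harvester
#' samples of one synthetic trial under the package's default study
#' conditions: a 120 m x 120 m field of six 20 m strips on a 2 m grid,
#' baseline yield mean 5,000 kg/ha with spherical spatial structure
#' (nugget 1,000, partial sill 160,000, range 40 m — a ~400 kg/ha spatial
#' standard deviation), 100 kg/ha (2%) measurement noise, and 3 m x 5 m
#' harvester sampling (~667 samples/ha).
#'
#' @param n_treatments number of treatments (2-5).
#' @param effects additive treatment effects, kg/ha; default all zero.
#' @param seed integer seed; baseline and noise draws are derived from it.
#' @param mean baseline mean, kg/ha.
#' @param vm baseline [variogram_model()].
#' @param noise_sd measurement noise, kg/ha.
#' @param width,height field dimensions, m.
#' @param pixel baseline grid pixel, m.
#' @param strip_width strip width, m.
#' @param layout,orientation see [trial_design()].
#' @param along_spacing,across_spacing see [sample_harvest_tracks()].
#' @param crs CRS of the simulated field (a metric default, UTM 23S).
#' @return list of class `simulated_trial`: `samples` ([sample_set()]),
#'   `area` ([study_area()]), `truth` ([field_truth()]), `design`.
#' @export
simulate_trial <- function(n_treatments = 2L, effects = NULL, seed = 42L,
                           mean = 5000,
                           vm = variogram_model("spherical", nugget = 1000,
                                                partial_sill = 160000, range_ = 40),
                           noise_sd = 100, width = 120, height = 120,
                           pixel = 2, strip_width = 20,
                           layout = "interleaved", orientation = "columns",
                           along_spacing = 3, across_spacing = 5,
                           crs = 32723) {
  ring <- rbind(c(0, 0), c(width, 0), c(width, height), c(0, height))
  area <- study_area(list(ring), crs = crs)
  design <- trial_design(area, n_treatments, strip_width, layout, orientation)
  spec <- grid_spec(c(0, 0, width, height), pixel)
  baseline <- simulate_gaussian_field(vm, spec, mean = mean,
                                      seed = seed, crs = crs)
  if (is.null(effects)) effects <- rep(0, n_treatments)
  if (is.null(names(effects))) names(effects) <- sprintf("T%d", seq_along(effects))
  truth <- field_truth(baseline, effects, noise_sd, vm)
  samples <- sample_harvest_tracks(truth, design, along_spacing,
                                   across_spacing, seed = seed + 1L)
  structure(list(samples = samples, area = area, truth = truth,
                 design = design, seed = as.integer(seed)),
            class = "simulated_trial")
}
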