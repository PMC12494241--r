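#' Pipeline configuration
#'
#' Bundles every tunable of a gain-mapping run. Defaults mirror common
#' yield-trial practice: 1.5 m pixels, linear semivariogram, 80/20 holdout,
#' global neighbourhood search with a 16-20 neighbour window.
#'
#' @param reference_treatment label of the reference treatment (default
#'   `"T1"`); gains are `reference - other`.
#' @param pixel interpolation pixel size, m.
#' @param model semivariogram family (see [variogram_model()]).
#' @param holdout_fraction training fraction per treatment, in (0, 1).
#' @param seed integer seed driving the random holdout selection.
#' @param n_lags,max_dist empirical-variogram controls (see
#'   [empirical_variogram()]).
#' @param neighborhood a [neighborhood_config()].
#' @param all_pairs compute gains for every treatment pair, not only
#'   reference-vs-others.
#' @param target_crs optional CRS to reproject inputs into before analysis;
#'   must be projected (metric).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_treatment = "T1", pixel = 1.5,
                            model = "linear", holdout_fraction = 0.8,
                            seed = 42L, n_lags = 100, max_dist = 1000,
                            neighborhood = neighborhood_config(),
                            all_pairs = FALSE, target_crs = NULL) {
  stopifnot_scalar_number(pixel, "pixel", positive = TRUE)
  if (!is.numeric(holdout_fraction) || holdout_fraction <= 0 || holdout_fraction >= 1)
    gg_stop("config", "holdout_fraction must lie in (0, 1)")
  model <- match.arg(model, c("linear", "exponential", "gaussian", "spherical"))
  structure(list(reference_treatment = reference_treatment, pixel = pixel,
                 model = model, holdout_fraction = holdout_fraction,
                 seed = as.integer(seed), n_lags = n_lags, max_dist = max_dist,
                 neighborhood = neighborhood, all_pairs = isTRUE(all_pairs),
                 target_crs = target_crs),
            class = "pipeline_config")
}

#' Seeded holdout split of one treatment's points
#'
#' Training indices are the first `round(fraction * n)` entries of a seeded
#' pseudo-random permutation (ties in the rounding go up); the test set is
#' the complement. At least one test point is always kept. Reproducible
#' given the subset order and the seed; the global RNG state is untouched.
#'
#' @param n number of points, or a data frame whose rows are split.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @examples
#' holdout_split(100, 0.8, seed = 1)$train |> length()   # 80
#' @export
holdout_split <- function(n, fraction = 0.8, seed = 42L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 5L) gg_stop("insufficient_data",
                      "need >= 5 points per treatment to hold out (got %d)", n)
  if (fraction <= 0 || fraction >= 1)
    gg_stop("config", "holdout fraction must lie in (0, 1)")
  n_train <- as.integer(floor(fraction * n + 0.5))   # round, ties up
  n_train <- min(n_train, n - 1L)                    # >= 1 test point
  if (n_train < 2L)
    gg_stop("insufficient_data", "training split of %d point(s) is unusable", n_train)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}

#' Residuals of withheld observations against a sampled surface
#'
#' `r_i = observed_i - estimated_i`, with pairs dropped where the estimate
#' is `NA` (nodata or outside the grid).
#'
#' @param observed,estimated equal-length value vectors.
#' @return numeric residual vector with attribute `kept` (logical vector of
#'   retained pairs).
#' @export
residuals_of <- function(observed, estimated) {
  if (length(observed) != length(estimated))
    gg_stop("config", "observed and estimated must be equal length")
  keep <- !is.na(observed) & !is.na(estimated)
  if (!any(keep)) gg_stop("empty_residual", "all evaluation pairs are masked")
  structure(observed[keep] - estimated[keep], kept = keep)
}

#' Residual-corrected surface
#'
#' Kriges the residuals of the holdout points onto the base surface's grid
#' and adds the two cellwise (base + error = final). The residual
#' semivariogram is refitted to the residuals with the same model family.
#' Residual points are snapped to the centre of their containing cell
#' before kriging: the residual is defined against the cell's value, so it
#' lives at cell resolution — this makes the final surface reproduce each
#' holdout observation exactly at its cell (see the methods vignette).
#'
#' @param base a [raster_grid()] (the training-split kriged estimate).
#' @param x,y residual point coordinates.
#' @param r residual values (observed - estimated).
#' @param family semivariogram family for the residual fit.
#' @param nb a [neighborhood_config()].
#' @param n_lags,max_dist empirical-variogram controls for the residual fit.
#' @return list: `error` (residual surface), `final` (base + error), and
#'   `model` (the fitted residual variogram).
#' @export
corrected_surface <- function(base, x, y, r, family = "linear",
                              nb = neighborhood_config(),
                              n_lags = 100, max_dist = 1000) {
  if (length(x) < 3L)
    gg_stop("insufficient_data", "need >= 3 residual points (got %d)", length(x))
  ci <- cell_index(base, x, y)
  x2 <- ifelse(ci$inside, base$origin_x + (ci$j - 0.5) * base$pixel, x)
  y2 <- ifelse(ci$inside, base$origin_y - (ci$i - 0.5) * base$pixel, y)
  # snapping can collapse several residuals into one cell; merge by mean
  key <- paste(x2, y2)
  if (anyDuplicated(key)) {
    agg <- tapply(r, key, mean)
    keep <- !duplicated(key)
    x2 <- x2[keep]; y2 <- y2[keep]
    r <- as.numeric(agg[key[keep]])
  }
  rv <- if (max(abs(r)) == 0) {
    variogram_model(if (family == "linear") "linear" else family,
                    nugget = 0,
                    partial_sill = if (family == "linear") NA else 0,
                    range_ = if (family == "linear") NA else 1,
                    slope = if (family == "linear") 0 else NA)
  } else {
    ev <- empirical_variogram(x2, y2, r, n_lags = n_lags, max_dist = max_dist)
    fit_variogram(ev, family)
  }
  spec <- structure(base[c("origin_x", "origin_y", "pixel", "ncols", "nrows")],
                    class = "grid_spec")
  err <- krige_grid(x2, y2, r, rv, spec, nb, crs = base$crs)
  fin <- base
  fin$values <- base$values + err$values
  list(error = err, final = fin, model = rv)
}

#' Run the full gain-mapping pipeline
#'
#' For every treatment: seeded 80/20 holdout, ordinary kriging of the
#' training points over the study-area envelope, sampling of the estimate
#' at the holdout points, kriging of the resulting residuals into an error
#' surface, summation into the final surface, and clipping to the study
#' area. Gains are cellwise differences between the reference treatment's
#' clipped final surface and each other treatment's, with summary
#' statistics per pair, plus RMSE% / Pearson-r holdout validation of each
#' final surface.
#'
#' @param s a [sample_set()] in a projected CRS (or with `target_crs` set
#'   in `cfg`).
#' @param a a [study_area()] in the same CRS.
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result`: per-treatment `surfaces`
#'   (`base`, `error`, `final`, `final_clipped`, `model`, `train`, `test`),
#'   `gains` (named `raster_grid`s), `stats` (named [raster_stats()]
#'   lists), `evaluation` (RMSE%/r of each treatment's base surface at its
#'   holdout points; the corrected final surface reproduces those points by
#'   construction), and `log` (run metadata:
#'   seed, pixel, model family, fitted variogram parameters per treatment).
#' @export
run_pipeline <- function(s, a, cfg = pipeline_config()) {
  if (!is.null(cfg$target_crs)) {
    s <- reproject_samples(s, cfg$target_crs)
    a <- reproject_area(a, cfg$target_crs)
  }
  if (!crs_is_projected(sample_crs(s)))
    gg_stop("crs", "samples are in a geographic CRS; set target_crs to a metric one")
  if (sample_crs(s) != a$crs)
    gg_stop("crs", "samples (EPSG:%d) and study area (EPSG:%d) CRS differ",
            sample_crs(s), a$crs)
  labels <- treatment_labels(s)
  if (!(cfg$reference_treatment %in% labels))
    gg_stop("config", "reference treatment '%s' is not a declared label (%s)",
            cfg$reference_treatment, paste(labels, collapse = ", "))

  spec <- grid_spec(area_bounds(a), cfg$pixel)
  subsets <- split_by_treatment(s)
  surfaces <- list()
  for (lab in labels) {
    sub <- subsets[[lab]]
    sp <- holdout_split(nrow(sub), cfg$holdout_fraction, cfg$seed)
    tr <- sub[sp$train, ]; te <- sub[sp$test, ]
    ev <- empirical_variogram(tr$x, tr$y, tr$value,
                              n_lags = cfg$n_lags, max_dist = cfg$max_dist)
    vm <- fit_variogram(ev, cfg$model)
    base <- krige_grid(tr$x, tr$y, tr$value, vm, spec, cfg$neighborhood,
                       crs = sample_crs(s))
    est_at_test <- sample_raster_at_points(base, te$x, te$y)
    r <- residuals_of(te$value, est_at_test)
    kept <- attr(r, "kept")
    corr <- corrected_surface(base, te$x[kept], te$y[kept], as.numeric(r),
                              family = cfg$model, nb = cfg$neighborhood,
                              n_lags = cfg$n_lags, max_dist = cfg$max_dist)
    final_clipped <- clip_to_area(corr$final, a)
    # the final surface reproduces the holdout observations by construction,
    # so model quality is measured on the pre-correction base surface
    evaluation <- tryCatch(evaluate_surface(base, te),
                           geogain_error = function(e) NULL)
    surfaces[[lab]] <- list(label = lab, base = base, error = corr$error,
                            final = corr$final, final_clipped = final_clipped,
                            model = vm, residual_model = corr$model,
                            train = sp$train, test = sp$test,
                            evaluation = evaluation)
  }

  ref <- cfg$reference_treatment
  pairs <- if (cfg$all_pairs) {
    utils::combn(labels, 2, simplify = FALSE)
  } else {
    lapply(setdiff(labels, ref), function(o) c(ref, o))
  }
  gains <- list(); stats <- list()
  for (p in pairs) {
    nm <- sprintf("%s_vs_%s", p[1], p[2])
    gains[[nm]] <- gain_surface(surfaces[[p[1]]]$final_clipped,
                                surfaces[[p[2]]]$final_clipped)
    stats[[nm]] <- raster_stats(gains[[nm]])
  }

  log <- list(seed = cfg$seed, pixel = cfg$pixel, model = cfg$model,
              holdout_fraction = cfg$holdout_fraction,
              reference_treatment = ref,
              crs = sample_crs(s),
              grid = list(ncols = spec$ncols, nrows = spec$nrows),
              variograms = lapply(surfaces, function(sf)
                unclass(sf$model)[c("family", "nugget", "partial_sill",
                                    "range_", "slope")]))
  structure(list(surfaces = surfaces, gains = gains, stats = stats,
                 evaluation = lapply(surfaces, `[[`, "evaluation"),
                 spec = spec, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d treatment surface(s), %d gain pair(s), grid %d x %d\n",
              length(x$surfaces), length(x$gains),
              x$spec$nrows, x$spec$ncols))
  for (nm in names(x$stats)) {
    st <- x$stats[[nm]]
    cat(sprintf("  gain %-12s mean=%.2f sd=%.2f min=%.2f max=%.2f (n=%d)\n",
                nm, st$mean, st$std, st$minimum, st$maximum, st$n_valid))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `<label>_final.tif` per treatment, `gain_<ref>_vs_<label>.tif`
#' per pair, the HTML gain-statistics report and a machine-readable
#' `run_log.json`.
#'
#' @param res a `pipeline_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lab in names(res$surfaces)) {
    p <- file.path(dir, paste0(lab, "_final.tif"))
    write_raster(res$surfaces[[lab]]$final_clipped, p)
    paths <- c(paths, p)
  }
  for (nm in names(res$gains)) {
    p <- file.path(dir, paste0("gain_", nm, ".tif"))
    write_raster(res$gains[[nm]], p)
    paths <- c(paths, p)
  }
  html <- file.path(dir, "statistics_of_gain.html")
  write_gain_report(res$stats, res$log, html)
  logp <- file.path(dir, "run_log.json")
  jsonlite::write_json(res$log, logp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, html, logp))
}
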