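#' Holdout validation metrics
#'
#' Root-mean-square error as a percentage of the observed mean,
#' `RMSE% = 100 * sqrt(sum((y - yhat)^2) / n) / (sum(y) / n)`, and
#' Pearson's correlation coefficient between observed and estimated values.
#' Both are computed over evaluation pairs where the estimate is valid.
#'
#' @param observed values measured in the field.
#' @param estimated corresponding estimated values.
#' @return `rmse_percent()`: a percentage `>= 0`; `pearson_r()`: a value in
#'   `[-1, 1]`.
#' @examples
#' rmse_percent(c(100, 100), c(90, 110))   # 10
#' pearson_r(c(1, 2, 3), c(3, 2, 1))       # -1
#' @export
rmse_percent <- function(observed, estimated) {
  n <- length(observed)
  if (n < 1L || length(estimated) != n)
    gg_stop("config", "observed and estimated must be equal-length, non-empty")
  m <- mean(observed)
  if (m == 0) gg_stop("zero_mean", "observed mean is zero; RMSE%% undefined")
  100 * sqrt(sum((observed - estimated)^2) / n) / m
}

#' @rdname rmse_percent
#' @export
pearson_r <- function(observed, estimated) {
  n <- length(observed)
  if (n < 2L || length(estimated) != n)
    gg_stop("config", "need >= 2 equal-length pairs for a correlation")
  if (stats::sd(observed) == 0 || stats::sd(estimated) == 0)
    gg_stop("constant_vector",
            "correlation undefined: at least one vector is constant")
  stats::cor(observed, estimated, method = "pearson")
}

#' Evaluate a surface against withheld observations
#'
#' Samples the surface at the evaluation points (nearest-cell lookup, no
#' interpolation), drops pairs falling on nodata cells or outside the grid,
#' and reports RMSE% and Pearson r with the usable pair count.
#'
#' @param g a [raster_grid()].
#' @param pts a [sample_set()] (or data frame with `x`, `y`, `value`) of
#'   withheld observations.
#' @return list of class `evaluation_result`: `rmse_percent`, `r`, `n`.
#' @export
evaluate_surface <- function(g, pts) {
  est <- sample_raster_at_points(g, pts)
  keep <- !is.na(est)
  obs <- pts$value[keep]; est <- est[keep]
  if (length(obs) < 2L)
    gg_stop("insufficient_data",
            "only %d evaluation point(s) fall on valid cells; need >= 2", length(obs))
  structure(list(rmse_percent = rmse_percent(obs, est),
                 r = pearson_r(obs, est),
                 n = length(obs)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> n=%d  RMSE%%=%.4f  r=%.4f\n",
              x$n, x$rmse_percent, x$r))
  invisible(x)
}
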