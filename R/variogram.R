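#' Semivariogram model
#'
#' One of the four standard isotropic families. With nugget `c0`, partial
#' sill `c` and range `a` (`slope` `b` for the linear family), the
#' semivariance at separation `h > 0` is
#' \describe{
#'   \item{linear}{`c0 + b * h`}
#'   \item{exponential}{`c0 + c * (1 - exp(-3 h / a))` (practical range `a`)}
#'   \item{gaussian}{`c0 + c * (1 - exp(-3 h^2 / a^2))`}
#'   \item{spherical}{`c0 + c * (1.5 (h/a) - 0.5 (h/a)^3)` for `h <= a`,
#'     `c0 + c` beyond}
#' }
#' and `gamma(0) = 0` by convention (the nugget is a discontinuity at the
#' origin, not a value at it) — this is what makes ordinary kriging an
#' exact interpolator at the data locations.
#'
#' @param family `"linear"`, `"exponential"`, `"gaussian"` or `"spherical"`.
#' @param nugget `c0 >= 0`, variable units squared.
#' @param partial_sill `c >= 0` (ignored by linear).
#' @param range_ `a > 0`, metres (ignored by linear).
#' @param slope `b >= 0`, units^2 per metre (linear only).
#' @return object of class `variogram_model`.
#' @examples
#' vm <- variogram_model("spherical", nugget = 0, partial_sill = 1, range_ = 50)
#' model_gamma(vm, c(0, 25, 50, 100))
#' @export
variogram_model <- function(family = c("linear", "exponential", "gaussian", "spherical"),
                            nugget = 0, partial_sill = NA_real_, range_ = NA_real_,
                            slope = NA_real_) {
  family <- match.arg(family)
  if (!is.finite(nugget) || nugget < 0)
    gg_stop("config", "nugget must be finite and >= 0")
  if (family == "linear") {
    if (!is.finite(slope) || slope < 0)
      gg_stop("config", "linear model needs slope >= 0")
    partial_sill <- NA_real_; range_ <- NA_real_
  } else {
    if (!is.finite(partial_sill) || partial_sill < 0)
      gg_stop("config", "%s model needs partial_sill >= 0", family)
    if (!is.finite(range_) || range_ <= 0)
      gg_stop("config", "%s model needs range_ > 0", family)
    slope <- NA_real_
  }
  structure(list(family = family, nugget = nugget, partial_sill = partial_sill,
                 range_ = range_, slope = slope),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  if (x$family == "linear")
    cat(sprintf("<variogram_model> linear: nugget=%.6g, slope=%.6g\n",
                x$nugget, x$slope))
  else
    cat(sprintf("<variogram_model> %s: nugget=%.6g, partial sill=%.6g, range=%.6g m\n",
                x$family, x$nugget, x$partial_sill, x$range_))
  invisible(x)
}

#' @rdname variogram_model
#' @param m a `variogram_model`.
#' @param h distances (m), `>= 0`; vectorised.
#' @export
model_gamma <- function(m, h) {
  if (any(h < 0)) gg_stop("config", "semivariogram distance h must be >= 0")
  g <- switch(m$family,
    linear      = m$nugget + m$slope * h,
    exponential = m$nugget + m$partial_sill * (1 - exp(-3 * h / m$range_)),
    gaussian    = m$nugget + m$partial_sill * (1 - exp(-3 * h^2 / m$range_^2)),
    spherical   = {
      hr <- pmin(h / m$range_, 1)
      m$nugget + m$partial_sill * (1.5 * hr - 0.5 * hr^3)
    })
  g[h == 0] <- 0
  g
}

# total sill (variance plateau); linear has none — callers supply a
# pseudo-sill where a finite variance is required.
total_sill <- function(m) {
  if (m$family == "linear") Inf else m$nugget + m$partial_sill
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Classical estimator
#' `gamma_hat(h_k) = (1 / (2 N(h_k))) * sum (z_i - z_j)^2` over point pairs
#' whose separation falls in lag bin `k`; bins partition `(0, max_dist]`
#' into `n_lags` equal intervals and empty bins are dropped. Model fitting
#' ([fit_variogram()]) additionally requires at least 3 non-empty bins.
#'
#' @param x,y,value coordinate and value vectors, or a data frame with those
#'   columns as `x`.
#' @param n_lags number of lag bins (>= 3). Default 100.
#' @param max_dist largest separation considered, m. Default 1000.
#' @param skip use every `skip`-th point (1 = all points). Subsampling knob
#'   for very dense data.
#' @param bin_width if given, bins are `bin_width`-wide intervals instead of
#'   `max_dist / n_lags` (the two common readings of a "lag" parameter).
#' @return object of class `empirical_variogram`: data frame with
#'   `lag_center`, `gamma_hat`, `pair_count`, plus attribute `max_dist`.
#' @export
empirical_variogram <- function(x, y = NULL, value = NULL, n_lags = 100,
                                max_dist = 1000, skip = 1L, bin_width = NULL) {
  if (is.data.frame(x)) { value <- x$value; y <- x$y; x <- x$x }
  stopifnot_scalar_number(max_dist, "max_dist", positive = TRUE)
  if (n_lags < 3L) gg_stop("config", "n_lags must be >= 3")
  if (skip > 1L) {
    idx <- seq(1L, length(x), by = as.integer(skip))
    x <- x[idx]; y <- y[idx]; value <- value[idx]
  }
  n <- length(x)
  if (n < 2L) gg_stop("degenerate_geometry", "need >= 2 points for a variogram")
  d <- stats::dist(cbind(x, y))
  if (max(d) == 0)
    gg_stop("degenerate_geometry", "all points are coincident")
  dv <- as.vector(d)
  sq <- as.vector(stats::dist(value))^2      # (z_i - z_j)^2 per pair
  keep <- dv > 0 & dv <= max_dist
  dv <- dv[keep]; sq <- sq[keep]
  width <- if (is.null(bin_width)) max_dist / n_lags else bin_width
  bin <- pmin(ceiling(dv / width), if (is.null(bin_width)) n_lags else ceiling(max_dist / width))
  cnt <- tabulate(bin)
  gsum <- rep(0, length(cnt))
  gs <- tapply(sq, bin, sum)
  gsum[as.integer(names(gs))] <- gs
  nonempty <- which(cnt > 0L)
  out <- data.frame(lag_center = (nonempty - 0.5) * width,
                    gamma_hat = gsum[nonempty] / (2 * cnt[nonempty]),
                    pair_count = cnt[nonempty])
  structure(out, max_dist = max_dist, class = c("empirical_variogram", "data.frame"))
}

# family-specific residual function for weighted least squares
vgm_from_par <- function(family, par) {
  if (family == "linear")
    variogram_model("linear", nugget = par[1], slope = par[2])
  else
    variogram_model(family, nugget = par[1], partial_sill = par[2], range_ = par[3])
}

#' Fit a semivariogram model to an empirical variogram
#'
#' Weighted least squares with weights proportional to the pair count of
#' each lag bin, minimised by Levenberg-Marquardt under box constraints at
#' zero, from five deterministic starting points spanning the empirical
#' sill and lag span; the best converged candidate is returned.
#'
#' @param ev an [empirical_variogram()].
#' @param family model family to fit (see [variogram_model()]).
#' @return fitted [variogram_model()], with attributes `wss` (weighted
#'   residual sum of squares) and `converged`.
#' @export
fit_variogram <- function(ev, family = c("linear", "exponential", "gaussian", "spherical")) {
  family <- match.arg(family)
  if (nrow(ev) < 3L)
    gg_stop("insufficient_structure", "need >= 3 non-empty bins to fit (got %d)", nrow(ev))
  h <- ev$lag_center; g <- ev$gamma_hat
  w <- sqrt(ev$pair_count / sum(ev$pair_count))
  s_hat <- max(g)                       # empirical sill scale
  hmax <- max(h)

  if (family == "linear") {
    # weighted linear regression gamma ~ c0 + b h with projection onto
    # {c0 >= 0, b >= 0}
    fit <- stats::lm.wfit(cbind(1, h), g, ev$pair_count)
    par <- unname(fit$coefficients)
    if (any(!is.finite(par)) || any(par < 0)) {
      cands <- list(c(max(0, par[1]), max(0, par[2])),
                    c(0, max(0, sum(ev$pair_count * g * h) / sum(ev$pair_count * h^2))),
                    c(max(0, stats::weighted.mean(g, ev$pair_count)), 0))
      wss <- vapply(cands, function(p) sum((w * (p[1] + p[2] * h - g))^2), numeric(1))
      par <- cands[[which.min(wss)]]
    }
    out <- variogram_model("linear", nugget = par[1], slope = par[2])
    attr(out, "wss") <- sum((w * (model_gamma(out, h) - g))^2)
    attr(out, "converged") <- TRUE
    return(out)
  }

  starts <- list(c(0,           s_hat,        hmax / 3),
                 c(0,           s_hat,        hmax * 2 / 3),
                 c(s_hat * 0.1, s_hat * 0.9,  hmax / 4),
                 c(s_hat * 0.5, s_hat * 0.5,  hmax / 2),
                 c(0,           s_hat * 1.5,  hmax))
  best <- NULL; best_wss <- Inf
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = pmax(p0, c(0, 1e-10 * s_hat, 1e-6 * hmax)),
        lower = c(0, 0, hmax * 1e-6),
        upper = c(Inf, Inf, hmax * 100),
        fn = function(p) w * (model_gamma(vgm_from_par(family, p), h) - g),
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    wss <- sum(res$fvec^2)
    if (wss < best_wss) { best_wss <- wss; best <- res$par }
  }
  if (is.null(best)) {
    e <- errorCondition("semivariogram fit failed from every start",
                        class = c("geogain_error_fit_failure", "geogain_error"))
    e$empirical <- ev
    stop(e)
  }
  # identifiability tie-break: a fitted range below the first lag makes the
  # model flat over every observed lag, so the nugget/sill split is
  # arbitrary — collapse the plateau into the nugget (pure-nugget reading)
  if (best[3] < min(h)) best <- c(best[1] + best[2], 0, min(h))
  out <- vgm_from_par(family, best)
  attr(out, "wss") <- sum((w * (model_gamma(out, h) - g))^2)
  attr(out, "converged") <- TRUE
  out
}
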