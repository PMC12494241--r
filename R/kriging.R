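#' Kriging neighbourhood configuration
#'
#' Defaults follow common practice for yield-monitor data: global search
#' with the nearest points capped at 20, a minimum of 16 neighbours, and a
#' 1,000 m maximum search distance honoured in local mode. In global mode
#' every training point is a candidate and only the `max_neighbors` cap
#' applies; in local mode candidates are restricted to
#' `max_search_distance`. Ties at identical distance are broken by lowest
#' point index, so output is deterministic.
#'
#' @param mode `"global"` or `"local"`.
#' @param max_search_distance search radius (m), used in local mode.
#' @param min_neighbors if fewer candidates than this are admissible, all
#'   available are used and a warning is raised.
#' @param max_neighbors cap on the neighbours entering the kriging system.
#' @return list of class `neighborhood_config`.
#' @export
neighborhood_config <- function(mode = c("global", "local"),
                                max_search_distance = 1000,
                                min_neighbors = 16L, max_neighbors = 20L) {
  mode <- match.arg(mode)
  min_neighbors <- as.integer(min_neighbors)
  max_neighbors <- as.integer(max_neighbors)
  if (min_neighbors < 1L) gg_stop("config", "min_neighbors must be >= 1")
  if (max_neighbors < min_neighbors)
    gg_stop("config", "max_neighbors (%d) < min_neighbors (%d)",
            max_neighbors, min_neighbors)
  if (mode == "local") stopifnot_scalar_number(max_search_distance,
                                               "max_search_distance", positive = TRUE)
  structure(list(mode = mode, max_search_distance = max_search_distance,
                 min_neighbors = min_neighbors, max_neighbors = max_neighbors),
            class = "neighborhood_config")
}

# Guard against a singular bordered system: a fitted variogram that is flat
# (zero nugget, zero sill/slope) carries no structure; pure-nugget OK —
# which reduces to the neighbourhood mean — is the defensible limit.
effective_model <- function(vm) {
  flat <- switch(vm$family,
    linear = vm$nugget + vm$slope == 0,
    vm$nugget + vm$partial_sill == 0)
  if (flat) variogram_model("exponential", nugget = 1, partial_sill = 0, range_ = 1)
  else vm
}

# Shared state for a kriging run: training coords/values, their pairwise
# semivariance matrix, and the selection machinery.
krige_context <- function(x, y, z, vm) {
  n <- length(x)
  if (n < 2L) gg_stop("degenerate_geometry", "need >= 2 training points")
  vm <- effective_model(vm)
  D <- as.matrix(stats::dist(cbind(x, y)))
  if (max(D) == 0) gg_stop("degenerate_geometry", "all training points coincident")
  G <- matrix(model_gamma(vm, as.vector(D)), n, n)
  list(x = x, y = y, z = z, n = n, vm = vm, G = G)
}

select_neighbors <- function(d, nb) {
  cand <- seq_along(d)
  if (nb$mode == "local") cand <- cand[d[cand] <= nb$max_search_distance]
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(d[cand], cand)]        # ties -> lowest index
  utils::head(ord, nb$max_neighbors)
}

# Solve the ordinary-kriging bordered system for one target given the
# context and the neighbour index set.
ok_solve <- function(ctx, idx, d0) {
  m <- length(idx)
  A <- rbind(cbind(ctx$G[idx, idx, drop = FALSE], 1), c(rep(1, m), 0))
  b <- c(model_gamma(ctx$vm, d0), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  lambda <- sol[seq_len(m)]
  list(estimate = sum(lambda * ctx$z[idx]),
       variance = sum(sol * b),            # lambda' gamma0 + mu
       weights = lambda, idx = idx)
}

#' Ordinary kriging at a single target location
#'
#' Selects up to `max_neighbors` nearest training points (all points in
#' global mode; within `max_search_distance` in local mode), solves the
#' ordinary-kriging system with the unbiasedness constraint
#' `sum(lambda) = 1`, and returns the estimate and kriging variance. With
#' fewer than `min_neighbors` admissible points all available are used with
#' a warning; with none, the result is `NA` (a nodata cell, not an error).
#'
#' @param x,y,z training coordinates and values.
#' @param vm a [variogram_model()].
#' @param target numeric `c(x, y)`.
#' @param nb a [neighborhood_config()].
#' @return list: `estimate`, `variance`, `weights`, `idx` (training indices
#'   used). `estimate` is `NA` when no neighbour is admissible.
#' @examples
#' vm <- variogram_model("spherical", nugget = 0, partial_sill = 1, range_ = 50)
#' krige_point(c(0, 10, 0), c(0, 0, 10), c(1, 2, 3), vm, c(5, 5),
#'             neighborhood_config(min_neighbors = 1))$estimate
#' @export
krige_point <- function(x, y, z, vm, target, nb = neighborhood_config()) {
  ctx <- krige_context(x, y, z, vm)
  d0 <- sqrt((x - target[1])^2 + (y - target[2])^2)
  idx <- select_neighbors(d0, nb)
  if (length(idx) == 0L)
    return(list(estimate = NA_real_, variance = NA_real_,
                weights = numeric(0), idx = integer(0)))
  if (length(idx) < nb$min_neighbors)
    gg_warn("few_neighbors", "only %d neighbour(s) available (minimum %d requested)",
            length(idx), nb$min_neighbors)
  sol <- ok_solve(ctx, idx, d0[idx])
  if (is.null(sol))
    gg_stop("singular_system",
            "singular kriging system at target (%.3f, %.3f)", target[1], target[2])
  sol
}

#' Ordinary kriging over a regular grid
#'
#' Evaluates [krige_point()] at every cell centre of `spec`. Cells with no
#' admissible neighbour are masked. The per-cell weight sums are returned
#' (attribute `weight_sums`) so the unbiasedness constraint can be audited.
#'
#' @param x,y,z training coordinates and values.
#' @param vm a [variogram_model()].
#' @param spec a [grid_spec()].
#' @param nb a [neighborhood_config()].
#' @param crs CRS identifier stamped on the output raster.
#' @return a [raster_grid()] of estimates with attributes `weight_sums` and
#'   `variance` (matrices of the same shape).
#' @export
krige_grid <- function(x, y, z, vm, spec, nb = neighborhood_config(), crs = 0L) {
  ctx <- krige_context(x, y, z, vm)
  cc <- grid_centers(spec)
  ncell <- spec$nrows * spec$ncols
  est <- rep(NA_real_, ncell)
  kvar <- rep(NA_real_, ncell)
  wsum <- rep(NA_real_, ncell)
  short <- 0L
  # distances from every training point to every cell centre, cells in
  # column-major raster order (matches matrix(est, nrows))
  DX <- outer(ctx$x, cc$x, "-"); DY <- outer(ctx$y, cc$y, "-")
  D0 <- sqrt(DX * DX + DY * DY)
  for (k in seq_len(ncell)) {
    d0 <- D0[, k]
    idx <- select_neighbors(d0, nb)
    if (length(idx) == 0L) next
    if (length(idx) < nb$min_neighbors) short <- short + 1L
    sol <- ok_solve(ctx, idx, d0[idx])
    if (is.null(sol))
      gg_stop("singular_system", "singular kriging system at cell %d", k)
    est[k] <- sol$estimate
    kvar[k] <- sol$variance
    wsum[k] <- sum(sol$weights)
  }
  if (short > 0L)
    gg_warn("few_neighbors", "%d cell(s) had fewer than %d neighbours; all available were used",
            short, nb$min_neighbors)
  g <- raster_grid(matrix(est, spec$nrows, spec$ncols),
                   spec$origin_x, spec$origin_y, spec$pixel, crs)
  attr(g, "variance") <- matrix(kvar, spec$nrows, spec$ncols)
  attr(g, "weight_sums") <- matrix(wsum, spec$nrows, spec$ncols)
  g
}
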