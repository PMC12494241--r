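#' Regular raster grid of estimates
#'
#' Row 1 is the northern edge (raster convention); cell (i, j) has its
#' centre at `x = origin_x + (j - 0.5) * pixel`,
#' `y = origin_y - (i - 0.5) * pixel`, with `origin_y` the *top* (maximum y)
#' edge. Nodata cells are stored as `NA` in `values`; every statistic and
#' surface operation ignores them.
#'
#' @param values numeric matrix (nrows x ncols), `NA` = nodata.
#' @param origin_x x of the left (west) edge, m.
#' @param origin_y y of the top (north) edge, m.
#' @param pixel cell size, m (> 0).
#' @param crs CRS identifier.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_x, origin_y, pixel, crs) {
  stopifnot_scalar_number(pixel, "pixel", positive = TRUE)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(list(values = values,
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 pixel = as.numeric(pixel),
                 nrows = nrow(values), ncols = ncol(values),
                 crs = crs_code(crs)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  nv <- sum(!is.na(x$values))
  cat(sprintf("<raster_grid> %d x %d cells, pixel %g m, CRS EPSG:%d, %d valid cell(s)\n",
              x$nrows, x$ncols, x$pixel, x$crs, nv))
  if (nv > 0)
    cat(sprintf("  value range: [%.6g, %.6g]\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Grid specification from bounds and pixel size
#'
#' Dimensions are `ceiling((max - min) / pixel)`, so the grid covers the
#' bounds padded east/north to a whole number of pixels.
#'
#' @param bounds numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param pixel cell size in metres.
#' @return list with `origin_x`, `origin_y` (top edge), `pixel`, `ncols`,
#'   `nrows`, class `grid_spec`.
#' @export
grid_spec <- function(bounds, pixel) {
  stopifnot_scalar_number(pixel, "pixel", positive = TRUE)
  bounds <- as.numeric(bounds)
  if (length(bounds) != 4L || bounds[3] <= bounds[1] || bounds[4] <= bounds[2])
    gg_stop("config", "bounds must be c(xmin, ymin, xmax, ymax) with xmax > xmin, ymax > ymin")
  ncols <- as.integer(ceiling((bounds[3] - bounds[1]) / pixel))
  nrows <- as.integer(ceiling((bounds[4] - bounds[2]) / pixel))
  structure(list(origin_x = bounds[1], origin_y = bounds[2] + nrows * pixel,
                 pixel = pixel, ncols = ncols, nrows = nrows),
            class = "grid_spec")
}

# cell centres in raster order (row-major, row 1 = north)
grid_centers <- function(spec) {
  xs <- spec$origin_x + (seq_len(spec$ncols) - 0.5) * spec$pixel
  ys <- spec$origin_y - (seq_len(spec$nrows) - 0.5) * spec$pixel
  list(x = rep(xs, each = spec$nrows), y = rep(ys, times = spec$ncols),
       xs = xs, ys = ys)
}

same_gridspec <- function(g1, g2) {
  isTRUE(all.equal(c(g1$origin_x, g1$origin_y, g1$pixel),
                   c(g2$origin_x, g2$origin_y, g2$pixel), tolerance = 1e-9)) &&
    g1$nrows == g2$nrows && g1$ncols == g2$ncols
}

# row/col of the cell containing each point; half-open cells
# x in [x0 + (j-1)p, x0 + jp), y in (ytop - ip, ytop - (i-1)p]
cell_index <- function(g, x, y) {
  j <- floor((x - g$origin_x) / g$pixel) + 1
  i <- ceiling((g$origin_y - y) / g$pixel)
  i[g$origin_y - y == 0] <- 1          # top edge belongs to row 1
  inside <- j >= 1 & j <= g$ncols & i >= 1 & i <= g$nrows &
    x >= g$origin_x & y <= g$origin_y
  list(i = as.integer(i), j = as.integer(j), inside = inside)
}

#' Sample a raster at point locations
#'
#' Returns the value of the cell containing each point — nearest-cell
#' lookup, no interpolation between cells (cells are half-open:
#' `x in [x0, x0 + pixel)`). Points outside the grid or on nodata cells
#' yield `NA`.
#'
#' @param g a [raster_grid()].
#' @param x,y point coordinates, or a [sample_set()] as `x`.
#' @return numeric vector of sampled values, `NA` where unsampleable.
#' @export
sample_raster_at_points <- function(g, x, y = NULL) {
  if (inherits(x, "sample_set") || (is.data.frame(x) && is.null(y))) {
    if (!is.null(attr(x, "crs")) && attr(x, "crs") != g$crs)
      gg_stop("crs", "points (EPSG:%d) and raster (EPSG:%d) CRS differ",
              attr(x, "crs"), g$crs)
    y <- x$y; x <- x$x
  }
  ci <- cell_index(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- ci$inside
  out[ok] <- g$values[cbind(ci$i[ok], ci$j[ok])]
  out
}

#' Clip a raster to the study area
#'
#' Masks every cell whose centre falls outside the polygon; cells inside
#' are unchanged and grid dimensions are preserved. Idempotent. A polygon
#' disjoint from the grid gives an all-masked grid with a warning.
#'
#' @param g a [raster_grid()].
#' @param a a [study_area()] in the same CRS.
#' @return clipped `raster_grid`.
#' @export
clip_to_area <- function(g, a) {
  if (a$crs != g$crs)
    gg_stop("crs", "study area (EPSG:%d) and raster (EPSG:%d) CRS differ",
            a$crs, g$crs)
  cc <- grid_centers(g)
  inside <- matrix(points_in_area(a, cc$x, cc$y), nrow = g$nrows)
  v <- g$values
  v[!inside] <- NA_real_
  if (!any(inside))
    gg_warn("empty_clip", "study area is disjoint from the raster: all cells masked")
  g$values <- v
  g
}

#' Gain surface: cellwise difference of two surfaces
#'
#' `ref - other` per cell; masked wherever either input is masked. Both
#' grids must share geometry and CRS.
#'
#' @param ref,other [raster_grid()]s on an identical grid.
#' @return `raster_grid` of gains (variable units).
#' @export
gain_surface <- function(ref, other) {
  if (!same_gridspec(ref, other) || ref$crs != other$crs)
    gg_stop("grid_mismatch", "gain requires identical grid geometry and CRS")
  out <- ref
  out$values <- ref$values - other$values
  out
}

#' Summary statistics of a surface
#'
#' Statistics over valid (non-nodata) cells only. The standard deviation is
#' the population form (divisor n), matching raster zonal-statistics
#' convention.
#'
#' @param g a [raster_grid()].
#' @return list of class `gain_stats`: `minimum`, `maximum`, `sum`, `mean`,
#'   `std`, `n_valid`.
#' @export
raster_stats <- function(g) {
  v <- g$values[!is.na(g$values)]
  n <- length(v)
  if (n == 0L) gg_stop("empty_raster", "raster has zero valid cells")
  m <- mean(v)
  structure(list(minimum = min(v), maximum = max(v), sum = sum(v),
                 mean = m, std = sqrt(sum((v - m)^2) / n), n_valid = n),
            class = "gain_stats")
}

#' @export
print.gain_stats <- function(x, ...) {
  cat(sprintf("<gain_stats> n=%d  min=%.6g  max=%.6g  mean=%.6g  std=%.6g  sum=%.6g\n",
              x$n_valid, x$minimum, x$maximum, x$mean, x$std, x$sum))
  invisible(x)
}
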