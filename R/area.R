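#' Study-area polygon
#'
#' A `study_area` delimits the experimental field: one or more polygon
#' features, each a list of rings (first ring = outer boundary, further
#' rings = holes, even-odd rule). Containment over features is union
#' semantics, so disjoint features form a multi-part area.
#'
#' @param features list of features; each feature is a list of rings; each
#'   ring an n x 2 numeric matrix of x/y vertices (closed or open — the
#'   closing vertex is optional).
#' @param crs CRS identifier.
#' @return object of class `study_area`.
#' @export
study_area <- function(features, crs) {
  if (!is.list(features) || length(features) == 0L)
    gg_stop("empty_input", "study area has no polygon features")
  features <- lapply(features, function(f) {
    if (is.matrix(f)) f <- list(f)
    lapply(f, function(r) {
      r <- as.matrix(r)
      if (ncol(r) != 2L || nrow(r) < 3L)
        gg_stop("geometry", "polygon ring needs >= 3 x/y vertices")
      # drop an explicit closing vertex
      if (nrow(r) > 3L && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
      storage.mode(r) <- "double"
      r
    })
  })
  a <- structure(list(features = features, crs = crs_code(crs)),
                 class = "study_area")
  if (area_of(a) <= 0)
    gg_stop("geometry", "study area has non-positive area")
  a
}

ring_area <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' @rdname study_area
#' @param a a `study_area`.
#' @export
area_of <- function(a) {
  sum(vapply(a$features, function(f) {
    outer <- ring_area(f[[1]])
    holes <- if (length(f) > 1L)
      sum(vapply(f[-1], ring_area, numeric(1))) else 0
    outer - holes
  }, numeric(1)))
}

#' @export
print.study_area <- function(x, ...) {
  nr <- sum(lengths(x$features))
  cat(sprintf("<study_area> %d feature(s), %d ring(s), area %.1f m^2, CRS EPSG:%d\n",
              length(x$features), nr, area_of(x), x$crs))
  invisible(x)
}

#' @rdname study_area
#' @export
area_bounds <- function(a) {
  xs <- unlist(lapply(a$features, function(f) lapply(f, function(r) r[, 1])))
  ys <- unlist(lapply(a$features, function(f) lapply(f, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Even-odd containment per feature (holes honoured), union across features.
# mgcv::in.out expects rings separated by NA rows.
points_in_area <- function(a, x, y) {
  pts <- cbind(as.numeric(x), as.numeric(y))
  inside <- rep(FALSE, nrow(pts))
  for (f in a$features) {
    bnd <- do.call(rbind, lapply(f, function(r) rbind(r, c(NA_real_, NA_real_))))
    bnd <- bnd[-nrow(bnd), , drop = FALSE]
    inside <- inside | mgcv::in.out(bnd, pts)
  }
  inside
}

#' Reproject a study area
#'
#' @param a a [study_area()].
#' @param target_crs target CRS identifier; must be projected (metric).
#' @return reprojected `study_area`.
#' @export
reproject_area <- function(a, target_crs) {
  check_metric_target(target_crs)
  from <- a$crs
  feats <- lapply(a$features, function(f) lapply(f, function(r) {
    p <- transform_xy(r[, 1], r[, 2], from, target_crs)
    cbind(p$x, p$y)
  }))
  study_area(feats, target_crs)
}
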