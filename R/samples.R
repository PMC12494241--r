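#' Georeferenced point samples
#'
#' A `sample_set` holds the point observations of one trial: easting/northing
#' in a projected CRS, the measured variable (e.g. yield in kg/ha) and a
#' treatment label per point. Between 2 and 5 treatment labels (the field
#' convention is T1..T5) must be declared and every point must carry one of
#' them.
#'
#' @param x,y numeric coordinate vectors (metres in `crs`, or degrees for a
#'   geographic source awaiting reprojection).
#' @param value numeric measured variable, finite.
#' @param treatment character treatment label per point.
#' @param crs CRS identifier (see [crs_code()]).
#' @param variable_name name of the measured variable (for reports).
#' @param treatment_labels declared labels in order; defaults to the labels
#'   in first-appearance order.
#' @param merge_duplicates merge points sharing a location (within 1e-9 m)
#'   and treatment by averaging their values; exact duplicates otherwise make
#'   the kriging matrix singular. Default `TRUE`.
#' @return object of class `sample_set`: a `data.frame` with columns
#'   `x`, `y`, `value`, `treatment` and attributes `crs`, `variable_name`,
#'   `treatment_labels`, `n_merged`.
#' @examples
#' s <- sample_set(c(0, 10, 0, 10), c(0, 0, 10, 10), c(5, 6, 7, 8),
#'                 c("T1", "T1", "T2", "T2"), crs = 32723)
#' nrow(s)
#' treatment_labels(s)
#' @export
sample_set <- function(x, y, value, treatment, crs,
                       variable_name = "value",
                       treatment_labels = NULL,
                       merge_duplicates = TRUE) {
  n <- length(x)
  if (n == 0L) gg_stop("empty_input", "sample set has zero points")
  if (length(y) != n || length(value) != n || length(treatment) != n)
    gg_stop("config", "x, y, value and treatment must have equal length")
  x <- as.numeric(x); y <- as.numeric(y); value <- as.numeric(value)
  treatment <- trimws(as.character(treatment))
  bad <- which(!is.finite(value))
  if (length(bad))
    gg_stop("record", "non-finite variable value at record(s) %s",
            paste(utils::head(bad, 5L), collapse = ", "))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    gg_stop("record", "non-finite coordinates present")

  if (is.null(treatment_labels)) treatment_labels <- unique(treatment)
  treatment_labels <- trimws(as.character(treatment_labels))
  if (length(treatment_labels) < 2L || length(treatment_labels) > 5L)
    gg_stop("config", "between 2 and 5 treatment labels required (got %d: %s)",
            length(treatment_labels), paste(treatment_labels, collapse = ", "))
  unknown <- setdiff(unique(treatment), treatment_labels)
  if (length(unknown))
    gg_stop("record", "treatment label(s) not in declared set {%s}: %s",
            paste(treatment_labels, collapse = ", "),
            paste(unknown, collapse = ", "))

  df <- data.frame(x = x, y = y, value = value, treatment = treatment,
                   stringsAsFactors = FALSE)
  n_merged <- 0L
  if (merge_duplicates) {
    key <- paste(sprintf("%.9f", df$x), sprintf("%.9f", df$y), df$treatment)
    if (anyDuplicated(key)) {
      agg <- tapply(df$value, key, mean)
      keep <- !duplicated(key)
      n_merged <- nrow(df) - sum(keep)
      df <- df[keep, , drop = FALSE]
      df$value <- as.numeric(agg[paste(sprintf("%.9f", df$x),
                                       sprintf("%.9f", df$y), df$treatment)])
      rownames(df) <- NULL
    }
  }
  structure(df,
            crs = crs_code(crs),
            variable_name = variable_name,
            treatment_labels = treatment_labels,
            n_merged = n_merged,
            class = c("sample_set", "data.frame"))
}

#' @rdname sample_set
#' @param s a `sample_set`.
#' @export
treatment_labels <- function(s) attr(s, "treatment_labels")

#' @rdname sample_set
#' @export
sample_crs <- function(s) attr(s, "crs")

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d points, variable '%s', CRS EPSG:%d\n",
              nrow(x), attr(x, "variable_name"), attr(x, "crs")))
  tab <- table(x$treatment)
  cat("  treatments:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (attr(x, "n_merged") > 0L)
    cat(sprintf("  %d duplicate-location point(s) merged by averaging\n",
                attr(x, "n_merged")))
  invisible(x)
}

#' Partition a sample set by treatment
#'
#' Splits the points into one subset per declared treatment label. Subsets
#' are disjoint and their union is the input; a declared label with no
#' points is an error (the trial cannot be analysed without it).
#'
#' @param s a [sample_set()].
#' @return named list of `sample_set`-like data frames, one per label, in
#'   declared label order.
#' @export
split_by_treatment <- function(s) {
  labels <- treatment_labels(s)
  out <- lapply(labels, function(lab) {
    sub <- s[s$treatment == lab, , drop = FALSE]
    if (nrow(sub) == 0L)
      gg_stop("missing_treatment", "declared treatment '%s' has no points", lab)
    rownames(sub) <- NULL
    sub
  })
  names(out) <- labels
  out
}

#' Reproject point samples to a metric CRS
#'
#' Transforms the coordinates into `target_crs`, which must be projected
#' (metric): kriging distances are meaningless in degrees. Values and
#' treatment labels are untouched.
#'
#' @param s a [sample_set()].
#' @param target_crs target CRS identifier; must be projected.
#' @return the reprojected `sample_set`.
#' @export
reproject_samples <- function(s, target_crs) {
  check_metric_target(target_crs)
  p <- transform_xy(s$x, s$y, attr(s, "crs"), target_crs)
  s$x <- p$x; s$y <- p$y
  attr(s, "crs") <- crs_code(target_crs)
  s
}
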