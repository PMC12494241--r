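#' Read point samples from GeoJSON or CSV
#'
#' GeoJSON: a FeatureCollection of Point features; the CRS is taken from a
#' legacy top-level `crs` member when present (named `"EPSG:<code>"` or an
#' OGC `urn:ogc:def:crs:EPSG::<code>`), else WGS84 (EPSG:4326) per the
#' GeoJSON convention. CSV: coordinate columns named by `x_field`/`y_field`
#' and an explicit `crs` argument are required.
#'
#' Treatment labels are collected in first-appearance order; exact
#' duplicate locations within a treatment are merged by averaging (see
#' [sample_set()]).
#'
#' @param path file path (`.geojson`/`.json` or `.csv`).
#' @param variable_field attribute holding the measured variable; must be
#'   numeric-parseable.
#' @param treatment_field attribute holding the treatment label.
#' @param x_field,y_field CSV coordinate column names.
#' @param crs CRS identifier; required for CSV, overrides the file for
#'   GeoJSON.
#' @param treatment_labels optionally, the declared labels (a label outside
#'   this set is an error).
#' @return a [sample_set()].
#' @export
read_point_samples <- function(path, variable_field, treatment_field,
                               x_field = "x", y_field = "y", crs = NULL,
                               treatment_labels = NULL) {
  if (!file.exists(path)) gg_stop("io", "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    if (is.null(feats) || length(feats) == 0L)
      gg_stop("empty_input", "no features in %s", path)
    gtypes <- vapply(feats, function(f) f$geometry$type %||% "", "")
    if (!all(gtypes == "Point"))
      gg_stop("geometry", "expected Point geometry, found: %s",
              paste(unique(setdiff(gtypes, "Point")), collapse = ", "))
    coords <- t(vapply(feats, function(f) as.numeric(unlist(f$geometry$coordinates)[1:2]),
                       numeric(2)))
    getprop <- function(field) {
      lapply(seq_along(feats), function(i) {
        v <- feats[[i]]$properties[[field]]
        if (is.null(v))
          gg_stop("missing_field", "field '%s' missing on feature %d", field, i)
        v
      })
    }
    vals <- getprop(variable_field)
    value <- suppressWarnings(as.numeric(unlist(vals)))
    bad <- which(!is.finite(value))
    if (length(bad))
      gg_stop("record", "non-numeric '%s' at feature(s) %s", variable_field,
              paste(utils::head(bad, 5L), collapse = ", "))
    treatment <- as.character(unlist(getprop(treatment_field)))
    file_crs <- geojson_crs(gj)
    crs <- if (is.null(crs)) file_crs else crs
  } else if (ext == "csv") {
    if (is.null(crs))
      gg_stop("config", "reading CSV points requires an explicit 'crs'")
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) == 0L) gg_stop("empty_input", "no rows in %s", path)
    for (f in c(x_field, y_field, variable_field, treatment_field))
      if (!f %in% names(df))
        gg_stop("missing_field", "column '%s' not found in %s (have: %s)",
                f, path, paste(names(df), collapse = ", "))
    value <- suppressWarnings(as.numeric(df[[variable_field]]))
    bad <- which(!is.finite(value))
    if (length(bad))
      gg_stop("record", "non-numeric '%s' at row(s) %s", variable_field,
              paste(utils::head(bad, 5L), collapse = ", "))
    coords <- cbind(as.numeric(df[[x_field]]), as.numeric(df[[y_field]]))
    treatment <- as.character(df[[treatment_field]])
  } else {
    gg_stop("io", "unsupported point format '.%s' (use GeoJSON or CSV)", ext)
  }
  sample_set(coords[, 1], coords[, 2], value, treatment, crs = crs,
             variable_name = variable_field,
             treatment_labels = treatment_labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

geojson_crs <- function(gj) {
  nm <- gj$crs$properties$name
  if (is.null(nm)) return(4326L)
  m <- regmatches(nm, regexec("EPSG:*:?([0-9]+)$", nm))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else 4326L
}

#' Read a study-area polygon from GeoJSON
#'
#' All Polygon/MultiPolygon features are combined with union semantics
#' (a multi-part area); rings beyond the first of a polygon are holes.
#'
#' @param path GeoJSON file path.
#' @param crs optional CRS identifier overriding the file's.
#' @return a [study_area()].
#' @export
read_study_area <- function(path, crs = NULL) {
  if (!file.exists(path)) gg_stop("io", "file not found: %s", path)
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats) && !is.null(gj$type) &&
      gj$type %in% c("Polygon", "MultiPolygon"))
    feats <- list(list(geometry = gj))
  if (is.null(feats) || length(feats) == 0L)
    gg_stop("empty_input", "no features in %s", path)
  ring_mat <- function(ring)
    t(vapply(ring, function(pt) as.numeric(unlist(pt)[1:2]), numeric(2)))
  features <- list()
  for (f in feats) {
    g <- f$geometry
    if (is.null(g$type) || !g$type %in% c("Polygon", "MultiPolygon"))
      gg_stop("geometry", "expected Polygon geometry, found '%s'",
              g$type %||% "NULL")
    polys <- if (g$type == "Polygon") list(g$coordinates) else g$coordinates
    for (p in polys) features <- c(features, list(lapply(p, ring_mat)))
  }
  study_area(features, crs = crs %||% geojson_crs(gj))
}

#' Write point samples to GeoJSON or CSV
#'
#' The CSV form writes `x`, `y`, the variable column and the treatment
#' column; the GeoJSON form embeds the CRS as a legacy `crs` member so the
#' file round-trips through [read_point_samples()].
#'
#' @param s a [sample_set()].
#' @param path output path; format chosen by extension.
#' @return invisibly, `path`.
#' @export
write_point_samples <- function(s, path) {
  ext <- tolower(tools::file_ext(path))
  vn <- attr(s, "variable_name")
  if (ext == "csv") {
    df <- data.frame(x = s$x, y = s$y, v = s$value, treatment = s$treatment)
    names(df)[3] <- vn
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext %in% c("geojson", "json")) {
    feats <- lapply(seq_len(nrow(s)), function(i) {
      props <- list(s$value[i], s$treatment[i])
      names(props) <- c(vn, "treatment")
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(s$x[i], s$y[i])),
           properties = props)
    })
    gj <- list(type = "FeatureCollection",
               crs = list(type = "name",
                          properties = list(name = sprintf("EPSG:%d", sample_crs(s)))),
               features = feats)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  } else {
    gg_stop("io", "unsupported point format '.%s'", ext)
  }
  invisible(path)
}

#' Write a study area to GeoJSON
#'
#' @param a a [study_area()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_study_area <- function(a, path) {
  feats <- lapply(a$features, function(f) {
    rings <- lapply(f, function(r) {
      r <- rbind(r, r[1, ])              # GeoJSON rings are closed
      lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = rings),
         properties = stats::setNames(list(), character(0)))
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = sprintf("EPSG:%d", a$crs))),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
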