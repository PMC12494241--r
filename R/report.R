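#' Write the "Statistics of Gain" HTML report
#'
#' Self-contained HTML: one table row per treatment pair with the gain
#' surface's minimum, maximum, sum, mean, standard deviation and valid-cell
#' count, preceded by the run parameters.
#'
#' @param stats named list of [raster_stats()] results; names label the
#'   pairs (e.g. `"T1_vs_T2"`).
#' @param meta list of run metadata shown as parameters (e.g. pixel size,
#'   model family, seed); may be empty.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gain_report <- function(stats, meta = list(), path) {
  if (length(stats) == 0L)
    gg_stop("config", "at least one gain-statistics entry required")
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) formatC(x, format = "g", digits = 10)
  meta <- Filter(function(v) is.atomic(v) && length(v) == 1L, meta)
  meta_rows <- if (length(meta)) paste0(
    "<tr><td>", esc(names(meta)), "</td><td>",
    esc(unlist(lapply(meta, format))), "</td></tr>", collapse = "\n") else ""
  stat_rows <- paste0(vapply(names(stats), function(nm) {
    s <- stats[[nm]]
    paste0("<tr><td>", esc(nm), "</td><td>", num(s$minimum), "</td><td>",
           num(s$maximum), "</td><td>", num(s$sum), "</td><td>",
           num(s$mean), "</td><td>", num(s$std), "</td><td>",
           s$n_valid, "</td></tr>")
  }, ""), collapse = "\n")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>Statistics of Gain</title>\n",
    "<style>body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:4px 10px;text-align:right}th{background:#eee}</style>",
    "</head>\n<body>\n<h1>Statistics of Gain</h1>\n",
    if (nzchar(meta_rows))
      paste0("<h2>Run parameters</h2>\n<table>\n", meta_rows, "\n</table>\n")
    else "",
    "<h2>Gain surfaces</h2>\n<table>\n<tr><th>Pair</th><th>Minimum</th>",
    "<th>Maximum</th><th>Sum</th><th>Mean</th><th>Std</th><th>Valid cells</th></tr>\n",
    stat_rows, "\n</table>\n</body></html>\n")
  ok <- tryCatch({ writeLines(html, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) gg_stop("io", "cannot write report to '%s'", path)
  invisible(path)
}
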