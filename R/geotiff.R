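# Minimal GeoTIFF I/O: single-band, uncompressed, little-endian, with
# ModelPixelScale/ModelTiepoint georeferencing, a GeoKey directory carrying
# the EPSG code, and the GDAL nodata tag. Covers exactly what the pipeline
# writes and reads back; not a general TIFF implementation.

TIFF_TYPES <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, DOUBLE = 12L)
TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
raw_dbl <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

GEOTIFF_NODATA <- -9999

#' Write a raster grid as GeoTIFF
#'
#' Single-band uncompressed GeoTIFF with the grid's geotransform
#' (pixel-is-area, tiepoint at the top-left corner), the EPSG code in the
#' GeoKey directory, and nodata cells stored as -9999 (also declared via
#' the GDAL nodata tag). `FLT4S` (float32, the common GIS default) loses
#' precision beyond ~7 significant digits; use `FLT8S` where bit-exact
#' doubles matter.
#'
#' @param g a [raster_grid()].
#' @param path output path.
#' @param datatype `"FLT4S"` (float32, default) or `"FLT8S"` (float64).
#' @return invisibly, `path`.
#' @export
write_raster <- function(g, path, datatype = c("FLT4S", "FLT8S")) {
  datatype <- match.arg(datatype)
  bps <- if (datatype == "FLT4S") 32L else 64L
  v <- g$values
  v[is.na(v)] <- GEOTIFF_NODATA
  px <- as.vector(t(v))                       # row-major, top row first
  nbytes <- length(px) * bps / 8L
  pad <- as.integer(nbytes %% 2L)
  ifd_off <- 8L + nbytes + pad

  code <- g$crs
  model_type <- if (!crs_is_projected(code)) 2L else 1L
  cs_key <- if (model_type == 1L) 3072L else 2048L
  geokeys <- c(1L, 1L, 0L, 3L,
               1024L, 0L, 1L, model_type,
               1025L, 0L, 1L, 1L,            # pixel-is-area
               cs_key, 0L, 1L, code)
  nodata_str <- charToRaw("-9999")
  nodata_str <- c(nodata_str, as.raw(0))     # NUL-terminated ASCII

  entries <- list(
    list(256L, TIFF_TYPES[["LONG"]], 1L, g$ncols),
    list(257L, TIFF_TYPES[["LONG"]], 1L, g$nrows),
    list(258L, TIFF_TYPES[["SHORT"]], 1L, bps),
    list(259L, TIFF_TYPES[["SHORT"]], 1L, 1L),
    list(262L, TIFF_TYPES[["SHORT"]], 1L, 1L),
    list(273L, TIFF_TYPES[["LONG"]], 1L, 8L),
    list(277L, TIFF_TYPES[["SHORT"]], 1L, 1L),
    list(278L, TIFF_TYPES[["LONG"]], 1L, g$nrows),
    list(279L, TIFF_TYPES[["LONG"]], 1L, nbytes),
    list(284L, TIFF_TYPES[["SHORT"]], 1L, 1L),
    list(339L, TIFF_TYPES[["SHORT"]], 1L, 3L),
    list(33550L, TIFF_TYPES[["DOUBLE"]], 3L, c(g$pixel, g$pixel, 0)),
    list(33922L, TIFF_TYPES[["DOUBLE"]], 6L,
         c(0, 0, 0, g$origin_x, g$origin_y, 0)),
    list(34735L, TIFF_TYPES[["SHORT"]], length(geokeys), geokeys),
    list(42113L, TIFF_TYPES[["ASCII"]], length(nodata_str), nodata_str))

  ifd_len <- 2L + length(entries) * 12L + 4L
  ext_off <- ifd_off + ifd_len
  ifd <- raw_u16(length(entries))
  ext <- raw(0)
  for (e in entries) {
    type <- e[[2]]; count <- e[[3]]
    payload <- switch(as.character(type),
      `2`  = as.raw(e[[4]]),
      `3`  = raw_u16(e[[4]]),
      `4`  = raw_u32(e[[4]]),
      `12` = raw_dbl(e[[4]]))
    ifd <- c(ifd, raw_u16(e[[1]]), raw_u16(type), raw_u32(count))
    if (length(payload) <= 4L) {
      ifd <- c(ifd, payload, raw(4L - length(payload)))
    } else {
      ifd <- c(ifd, raw_u32(ext_off + length(ext)))
      if (length(payload) %% 2L) payload <- c(payload, as.raw(0))
      ext <- c(ext, payload)
    }
  }
  ifd <- c(ifd, raw_u32(0L))                  # no next IFD

  con <- tryCatch(file(path, "wb"), error = function(e)
    gg_stop("io", "cannot open '%s' for writing", path),
    warning = function(e) gg_stop("io", "cannot open '%s' for writing", path))
  on.exit(close(con))
  writeBin(c(charToRaw("II"), raw_u16(42L), raw_u32(ifd_off)), con)
  writeBin(px, con, size = bps / 8L, endian = "little")
  if (pad) writeBin(as.raw(0), con)
  writeBin(c(ifd, ext), con)
  invisible(path)
}

read_ifd_entry <- function(raw, pos) {
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  tag <- u16(pos); type <- u16(pos + 2); count <- u32(pos + 4)
  size <- TIFF_TYPE_SIZE[[as.character(type)]] * count
  src <- if (size <= 4) pos + 8 else u32(pos + 8) + 1
  bytes <- raw[src:(src + size - 1)]
  value <- switch(as.character(type),
    `1` = as.integer(bytes),
    `2` = rawToChar(bytes[bytes != as.raw(0)]),
    `3` = readBin(bytes, "integer", n = count, size = 2,
                  endian = "little", signed = FALSE),
    `4` = readBin(bytes, "integer", n = count, size = 4, endian = "little"),
    `12` = readBin(bytes, "double", n = count, size = 8, endian = "little"),
    NULL)
  list(tag = tag, value = value)
}

#' Read a GeoTIFF written by [write_raster()]
#'
#' Understands single-band uncompressed little-endian GeoTIFF with IEEE
#' float32/float64 samples; nodata cells (per the GDAL nodata tag, default
#' -9999) become `NA`.
#'
#' @param path GeoTIFF path.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) gg_stop("io", "file not found: %s", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" ||
      readBin(raw[3:4], "integer", size = 2, endian = "little") != 42L)
    gg_stop("io", "'%s' is not a little-endian TIFF", path)
  ifd_off <- readBin(raw[5:8], "integer", size = 4, endian = "little") + 1
  n_entries <- readBin(raw[ifd_off:(ifd_off + 1)], "integer", size = 2,
                       endian = "little", signed = FALSE)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- read_ifd_entry(raw, ifd_off + 2 + (k - 1) * 12)
    tags[[as.character(e$tag)]] <- e$value
  }
  need <- function(tag) tags[[as.character(tag)]] %||%
    gg_stop("io", "required TIFF tag %d missing in %s", tag, path)
  ncols <- need(256); nrows <- need(257)
  bps <- need(258)
  if ((tags[["259"]] %||% 1L) != 1L)
    gg_stop("io", "compressed TIFF not supported (%s)", path)
  if (!(bps %in% c(32L, 64L)) || (tags[["339"]] %||% 3L) != 3L)
    gg_stop("io", "only IEEE float32/float64 samples supported (%s)", path)
  offsets <- need(273); counts <- need(279)
  rps <- tags[["278"]] %||% nrows
  words <- bps / 8L
  px <- numeric(0)
  for (sidx in seq_along(offsets)) {
    at <- offsets[sidx] + 1
    px <- c(px, readBin(raw[at:(at + counts[sidx] - 1)], "double",
                        n = counts[sidx] / words, size = words,
                        endian = "little"))
  }
  if (length(px) != nrows * ncols)
    gg_stop("io", "pixel count mismatch in %s", path)
  scale <- need(33550); tie <- need(33922)
  if (abs(scale[1] - scale[2]) > 1e-9 * scale[1])
    gg_stop("io", "non-square pixels not supported (%s)", path)
  geo <- tags[["34735"]]
  code <- 0L
  if (!is.null(geo) && length(geo) >= 4) {
    nk <- geo[4]
    for (k in seq_len(nk)) {
      key <- geo[4 * k + 1:4]
      if (key[1] %in% c(3072L, 2048L)) code <- key[4]
    }
  }
  nodata <- suppressWarnings(as.numeric(tags[["42113"]] %||% NA))
  v <- matrix(px, nrows, ncols, byrow = TRUE)
  if (is.finite(nodata)) {
    tol <- if (bps == 32L) 1e-3 else 0
    v[abs(v - nodata) <= tol] <- NA_real_
  }
  raster_grid(v, origin_x = tie[4] - tie[1] * scale[1],
              origin_y = tie[5] + tie[2] * scale[2],
              pixel = scale[1], crs = code)
}
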