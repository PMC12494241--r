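#' Coordinate reference systems
#'
#' CRS identifiers are EPSG codes, given as `"EPSG:32723"` or a bare integer.
#' The package distinguishes geographic (degree) from projected (metric)
#' systems: all kriging requires metric coordinates, so geographic targets
#' are rejected at reprojection time. Transformations are implemented for
#' WGS84 longitude/latitude (EPSG:4326) to and from the WGS84 UTM zones
#' (EPSG:32601-32660 north, 32701-32760 south) via the transverse-Mercator
#' projection; any other projected EPSG code is accepted as an opaque metric
#' identifier, valid only for data already expressed in it.
#'
#' @param crs a CRS identifier (`"EPSG:<code>"` string or integer code).
#' @return `crs_code()` returns the integer EPSG code; `crs_is_projected()`
#'   a logical.
#' @examples
#' crs_code("EPSG:32723")
#' crs_is_projected(4326)
#' @name crs
NULL

#' @rdname crs
#' @export
crs_code <- function(crs) {
  if (is.numeric(crs) && length(crs) == 1L && is.finite(crs)) return(as.integer(crs))
  if (is.character(crs) && length(crs) == 1L) {
    m <- regmatches(crs, regexec("^(?:EPSG|epsg):?([0-9]+)$", crs))[[1]]
    if (length(m) == 2L) return(as.integer(m[2]))
  }
  gg_stop("crs", "cannot interpret CRS identifier '%s' (use 'EPSG:<code>')",
          paste(format(crs), collapse = ","))
}

# Geographic systems carry degree coordinates; everything else is treated as
# projected/metric. Only the common geographic codes are recognised.
GEOGRAPHIC_EPSG <- c(4326L, 4269L, 4267L, 4258L, 4674L)

#' @rdname crs
#' @export
crs_is_projected <- function(crs) {
  code <- crs_code(crs)
  !(code %in% GEOGRAPHIC_EPSG || (code >= 4001L && code <= 4999L))
}

utm_zone_params <- function(code) {
  if (code >= 32601L && code <= 32660L)
    list(zone = code - 32600L, north = TRUE)
  else if (code >= 32701L && code <= 32760L)
    list(zone = code - 32700L, north = FALSE)
  else NULL
}

# --- transverse Mercator (Krueger series, WGS84) ------------------------
# Series coefficients to n^6 give sub-millimetre accuracy within a UTM
# zone, so round-trips close to ~1e-9 degrees.

.tm_const <- local({
  a <- 6378137.0
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4; n5 <- n^5; n6 <- n^6
  A <- a / (1 + n) * (1 + n2 / 4 + n4 / 64 + n6 / 256)
  alpha <- c(
    n / 2 - 2 * n2 / 3 + 5 * n3 / 16 + 41 * n4 / 180 - 127 * n5 / 288 + 7891 * n6 / 37800,
    13 * n2 / 48 - 3 * n3 / 5 + 557 * n4 / 1440 + 281 * n5 / 630 - 1983433 * n6 / 1935360,
    61 * n3 / 240 - 103 * n4 / 140 + 15061 * n5 / 26880 + 167603 * n6 / 181440,
    49561 * n4 / 161280 - 179 * n5 / 168 + 6601661 * n6 / 7257600,
    34729 * n5 / 80640 - 3418889 * n6 / 1995840,
    212378941 * n6 / 319334400)
  beta <- c(
    n / 2 - 2 * n2 / 3 + 37 * n3 / 96 - n4 / 360 - 81 * n5 / 512 + 96199 * n6 / 604800,
    n2 / 48 + n3 / 15 - 437 * n4 / 1440 + 46 * n5 / 105 - 1118711 * n6 / 3870720,
    17 * n3 / 480 - 37 * n4 / 840 - 209 * n5 / 4480 + 5569 * n6 / 90720,
    4397 * n4 / 161280 - 11 * n5 / 504 - 830251 * n6 / 7257600,
    4583 * n5 / 161280 - 108847 * n6 / 3991680,
    20648693 * n6 / 638668800)
  delta <- c(  # inverse conformal-latitude series
    2 * n - 2 * n2 / 3 - 2 * n3 + 116 * n4 / 45 + 26 * n5 / 45 - 2854 * n6 / 675,
    7 * n2 / 3 - 8 * n3 / 5 - 227 * n4 / 45 + 2704 * n5 / 315 + 2323 * n6 / 945,
    56 * n3 / 15 - 136 * n4 / 35 - 1262 * n5 / 105 + 73814 * n6 / 2835,
    4279 * n4 / 630 - 332 * n5 / 35 - 399572 * n6 / 14175,
    4174 * n5 / 315 - 144838 * n6 / 6237,
    601676 * n6 / 22275)
  list(n = n, A = A, alpha = alpha, beta = beta, delta = delta, k0 = 0.9996)
})

utm_forward <- function(lon, lat, zone, north) {
  cc <- .tm_const
  lam0 <- (-183 + 6 * zone) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lam0
  e2n <- 2 * sqrt(cc$n) / (1 + cc$n)
  t <- sinh(atanh(sin(phi)) - e2n * atanh(e2n * sin(phi)))
  xi0 <- atan2(t, cos(lam))
  eta0 <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  xi <- xi0; eta <- eta0
  for (j in 1:6) {
    xi  <- xi  + cc$alpha[j] * sin(2 * j * xi0) * cosh(2 * j * eta0)
    eta <- eta + cc$alpha[j] * cos(2 * j * xi0) * sinh(2 * j * eta0)
  }
  list(x = 500000 + cc$k0 * cc$A * eta,
       y = (if (north) 0 else 1e7) + cc$k0 * cc$A * xi)
}

utm_inverse <- function(x, y, zone, north) {
  cc <- .tm_const
  lam0 <- (-183 + 6 * zone) * pi / 180
  xi <- (y - (if (north) 0 else 1e7)) / (cc$k0 * cc$A)
  eta <- (x - 500000) / (cc$k0 * cc$A)
  xi0 <- xi; eta0 <- eta
  for (j in 1:6) {
    xi0  <- xi0  - cc$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta0 <- eta0 - cc$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  chi <- asin(pmin(1, pmax(-1, sin(xi0) / cosh(eta0))))
  phi <- chi
  for (j in 1:6) phi <- phi + cc$delta[j] * sin(2 * j * chi)
  lam <- atan2(sinh(eta0), cos(xi0))
  list(lon = (lam + lam0) * 180 / pi, lat = phi * 180 / pi)
}

#' Transform coordinates between supported CRSs
#'
#' Vectorised transform of x/y pairs. Identity when source and target codes
#' match. Supported paths: EPSG:4326 to/from WGS84 UTM, and UTM zone to UTM
#' zone (through geographic coordinates). For geographic input `x` is
#' longitude and `y` latitude, in degrees.
#'
#' @param x,y numeric coordinate vectors.
#' @param from,to CRS identifiers (see [crs_code()]).
#' @return list with transformed `x` and `y`.
#' @export
transform_xy <- function(x, y, from, to) {
  from <- crs_code(from); to <- crs_code(to)
  if (from == to) return(list(x = x, y = y))
  fu <- utm_zone_params(from); tu <- utm_zone_params(to)
  if (from == 4326L && !is.null(tu)) {
    p <- utm_forward(x, y, tu$zone, tu$north)
    return(list(x = p$x, y = p$y))
  }
  if (!is.null(fu) && to == 4326L) {
    p <- utm_inverse(x, y, fu$zone, fu$north)
    return(list(x = p$lon, y = p$lat))
  }
  if (!is.null(fu) && !is.null(tu)) {
    g <- utm_inverse(x, y, fu$zone, fu$north)
    p <- utm_forward(g$lon, g$lat, tu$zone, tu$north)
    return(list(x = p$x, y = p$y))
  }
  gg_stop("crs", paste0(
    "no transformation path from EPSG:%d to EPSG:%d ",
    "(supported: WGS84 lon/lat <-> WGS84 UTM zones)"), from, to)
}

check_metric_target <- function(target_crs) {
  if (!crs_is_projected(target_crs))
    gg_stop("crs", "target CRS EPSG:%d is geographic (degrees); kriging requires a projected, metric CRS",
            crs_code(target_crs))
  invisible(TRUE)
}
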