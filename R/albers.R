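# Ellipsoidal Albers equal-area conic projection (Snyder's formulas).
# Defaults are the North America Albers Equal Area Conic system
# (ESRI:102008): GRS80 ellipsoid, standard parallels 20N and 60N,
# latitude of origin 40N, central meridian 96W.

.albers_params <- function(lon0, lat0, lat1, lat2, a, f) {
  e2 <- 2 * f - f^2
  e <- sqrt(e2)
  qf <- function(phi) {
    s <- sin(phi)
    (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) *
                  log((1 - e * s) / (1 + e * s)))
  }
  mf <- function(phi) cos(phi) / sqrt(1 - e2 * sin(phi)^2)
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180; p0 <- lat0 * pi / 180
  m1 <- mf(p1); m2 <- mf(p2)
  q1 <- qf(p1); q2 <- qf(p2); q0 <- qf(p0)
  n <- (m1^2 - m2^2) / (q2 - q1)
  C <- m1^2 + n * q1
  list(a = a, e = e, e2 = e2, lon0 = lon0, n = n, C = C,
       rho0 = a * sqrt(C - n * q0) / n, qf = qf)
}

.albers_default <- function() {
  .albers_params(lon0 = -96, lat0 = 40, lat1 = 20, lat2 = 60,
                 a = 6378137, f = 1 / 298.257222101)
}

#' Forward Albers equal-area projection
#'
#' Projects geographic coordinates to planar metres in the North America
#' Albers Equal Area Conic system (ESRI:102008).
#'
#' @param lon,lat Numeric vectors, decimal degrees.
#' @return Data frame with columns `x`, `y` (metres).
#' @export
albers_forward <- function(lon, lat) {
  if (any(!is.finite(lon) | !is.finite(lat)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180)) {
    bad <- which(!is.finite(lon) | !is.finite(lat) |
                   abs(lat) > 90 | abs(lon) > 180)
    stop("coordinates out of range at position(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  p <- .albers_default()
  phi <- lat * pi / 180
  rho <- p$a * sqrt(p$C - p$n * p$qf(phi)) / p$n
  th <- p$n * (lon - p$lon0) * pi / 180
  data.frame(x = rho * sin(th), y = p$rho0 - rho * cos(th))
}

#' Inverse Albers equal-area projection
#'
#' @param x,y Numeric vectors, metres in ESRI:102008.
#' @return Data frame with columns `lon`, `lat` (decimal degrees).
#' @export
albers_inverse <- function(x, y) {
  p <- .albers_default()
  rho <- sqrt(x^2 + (p$rho0 - y)^2)
  th <- atan2(x, p$rho0 - y)
  q <- (p$C - (rho * p$n / p$a)^2) / p$n
  phi <- asin(pmin(1, pmax(-1, q / 2)))
  for (i in 1:30) {  # fixed-point iteration, converges in a handful of steps
    s <- sin(phi)
    phi <- phi + (1 - p$e2 * s^2)^2 / (2 * cos(phi)) *
      (q / (1 - p$e2) - s / (1 - p$e2 * s^2) +
         (1 / (2 * p$e)) * log((1 - p$e * s) / (1 + p$e * s)))
  }
  data.frame(lon = p$lon0 + th / p$n * 180 / pi, lat = phi * 180 / pi)
}

#' Attach projected coordinates to site summaries
#'
#' Adds planar `x`/`y` columns (metres, ESRI:102008) from `longitude` and
#' `latitude`. Downstream interpolation distances are planar Euclidean in
#' this equal-area CRS.
#'
#' @param sites Data frame with `longitude` and `latitude` columns.
#' @param crs CRS label; only `"ESRI:102008"` is supported.
#' @return `sites` with `x` and `y` columns added.
#' @export
project_points <- function(sites, crs = "ESRI:102008") {
  if (!identical(crs, "ESRI:102008")) {
    stop("only the ESRI:102008 working CRS is supported", call. = FALSE)
  }
  if (nrow(sites) == 0L) {
    sites$x <- numeric(0); sites$y <- numeric(0)
    return(sites)
  }
  assert_cols(sites, c("longitude", "latitude"), "sites")
  xy <- albers_forward(sites$longitude, sites$latitude)
  sites$x <- xy$x
  sites$y <- xy$y
  sites
}
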