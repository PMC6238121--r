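# Colony-centred Lambert azimuthal equal-area projection on the authalic
# sphere. Geodetic latitudes are first converted to authalic latitudes so that
# distances and areas within a few hundred km of the projection centre agree
# with ellipsoidal (WGS84) geodesics to well under 1%.

# WGS84
.WGS84_A  <- 6378.137          # semi-major axis, km
.WGS84_E2 <- 0.00669437999014  # first eccentricity squared
.AUTH_R   <- 6371.0071810      # authalic radius, km

.authalic_lat <- function(lat_rad) {
  e2 <- .WGS84_E2
  # series expansion of the authalic latitude in powers of e2
  lat_rad -
    (e2 / 3 + 31 * e2^2 / 180 + 59 * e2^3 / 560) * sin(2 * lat_rad) +
    (17 * e2^2 / 360 + 61 * e2^3 / 1260) * sin(4 * lat_rad) -
    (383 * e2^3 / 45360) * sin(6 * lat_rad)
}

.authalic_lat_inv <- function(beta_rad) {
  e2 <- .WGS84_E2
  beta_rad +
    (e2 / 3 + 31 * e2^2 / 180 + 517 * e2^3 / 5040) * sin(2 * beta_rad) +
    (23 * e2^2 / 360 + 251 * e2^3 / 3780) * sin(4 * beta_rad) +
    (761 * e2^3 / 45360) * sin(6 * beta_rad)
}

#' Project longitude/latitude to a colony-centred equal-area plane
#'
#' Lambert azimuthal equal-area projection centred on the colony, on the
#' authalic sphere of WGS84. The colony maps to (0, 0); `x` points east and
#' `y` north, both in kilometres. The projection is exactly invertible (see
#' [plane_to_lonlat()]) and preserves pairwise distances to well within 1%
#' out to a few hundred kilometres from the centre.
#'
#' @param lon,lat numeric vectors of geodetic coordinates in decimal degrees.
#' @param clon,clat colony (centre) longitude and latitude in degrees.
#' @return a two-column matrix with columns `x`, `y` in km.
#' @seealso [plane_to_lonlat()]
#' @export
lonlat_to_plane <- function(lon, lat, clon, clat) {
  stopifnot(length(clon) == 1, length(clat) == 1,
            abs(clat) <= 90, abs(clon) <= 180)
  phi  <- .authalic_lat(lat * pi / 180)
  phi0 <- .authalic_lat(clat * pi / 180)
  dlam <- (lon - clon) * pi / 180
  R <- .AUTH_R
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  cosc <- pmin(1, pmax(-1, cosc))
  k <- sqrt(2 / pmax(1 + cosc, 1e-15))
  x <- R * k * cos(phi) * sin(dlam)
  y <- R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  at_centre <- cosc > 1 - 1e-15
  x[at_centre] <- 0
  y[at_centre] <- 0
  cbind(x = x, y = y)
}

#' Inverse colony-centred projection
#'
#' Maps planar `x`/`y` kilometre coordinates (as produced by
#' [lonlat_to_plane()]) back to geodetic longitude/latitude degrees.
#'
#' @param x,y numeric vectors, km east/north of the colony.
#' @inheritParams lonlat_to_plane
#' @return a two-column matrix with columns `lon`, `lat` in degrees.
#' @export
plane_to_lonlat <- function(x, y, clon, clat) {
  R <- .AUTH_R
  phi0 <- .authalic_lat(clat * pi / 180)
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * R)))
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  safe_rho <- ifelse(rho < 1e-12, 1, rho)
  phi <- asin(pmin(1, pmax(-1, cosc * sin(phi0) + y * sinc * cos(phi0) / safe_rho)))
  lam <- atan2(x * sinc, safe_rho * cos(phi0) * cosc - y * sin(phi0) * sinc)
  phi[rho < 1e-12] <- phi0
  lam[rho < 1e-12] <- 0
  lat <- .authalic_lat_inv(phi) * 180 / pi
  lon <- clon + lam * 180 / pi
  lon <- ((lon + 180) %% 360) - 180
  cbind(lon = lon, lat = lat)
}
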