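#' Azimuthal-equidistant projection of geographic coordinates
#'
#' Projects longitude/latitude (WGS84 degrees, treated as spherical with
#' R = 6371 km) onto a plane centred at `origin`. The projection preserves
#' great-circle distance and azimuth from the origin, so the planar distance of
#' any point from (0, 0) equals its great-circle distance from the origin —
#' exactly the property needed for net squared displacement.
#'
#' @param lon,lat Numeric vectors of coordinates in decimal degrees.
#' @param origin Length-2 numeric `c(lon, lat)` of the projection centre.
#' @return A data.frame with columns `x_km`, `y_km`.
#' @seealso [plane_to_lonlat()] for the inverse.
#' @examples
#' project_to_plane(1, 0, origin = c(0, 0))  # ~111.19 km east
#' @export
project_to_plane <- function(lon, lat, origin) {
  check_lonlat(lon, lat)
  check_lonlat(origin[1], origin[2])
  lon0 <- origin[1] * pi / 180
  lat0 <- origin[2] * pi / 180
  lam <- lon * pi / 180
  phi <- lat * pi / 180

  cosc <- sin(lat0) * sin(phi) + cos(lat0) * cos(phi) * cos(lam - lon0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  # k = c / sin(c), with limit 1 at the origin
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lon0)
  y <- EARTH_RADIUS_KM * k *
    (cos(lat0) * sin(phi) - sin(lat0) * cos(phi) * cos(lam - lon0))
  data.frame(x_km = x, y_km = y)
}

#' Inverse azimuthal-equidistant projection
#'
#' Maps planar kilometres back to longitude/latitude for the same `origin`
#' used by [project_to_plane()].
#'
#' @param x_km,y_km Numeric vectors of planar coordinates (km).
#' @param origin Length-2 numeric `c(lon, lat)` of the projection centre.
#' @return A data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
plane_to_lonlat <- function(x_km, y_km, origin) {
  lon0 <- origin[1] * pi / 180
  lat0 <- origin[2] * pi / 180
  rho <- sqrt(x_km^2 + y_km^2)
  c_ang <- rho / EARTH_RADIUS_KM
  near0 <- rho < 1e-12
  rho_safe <- ifelse(near0, 1, rho)
  phi <- asin(cos(c_ang) * sin(lat0) +
                y_km * sin(c_ang) * cos(lat0) / rho_safe)
  lam <- lon0 + atan2(x_km * sin(c_ang),
                      rho_safe * cos(lat0) * cos(c_ang) -
                        y_km * sin(lat0) * sin(c_ang))
  lon <- ifelse(near0, lon0, lam) * 180 / pi
  lat <- ifelse(near0, lat0, phi) * 180 / pi
  # normalise longitude into [-180, 180]
  lon <- ((lon + 180) %% 360) - 180
  data.frame(lon = lon, lat = lat)
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (any(abs(lat) > 90)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(abs(lon) > 180)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}
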