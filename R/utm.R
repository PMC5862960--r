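# Transverse Mercator (UTM) on the WGS84 ellipsoid, standard series
# expansion. Accuracy is well under 1 m within a zone, which is all the
# planar home-range work requires.

WGS84_A <- 6378137
WGS84_F <- 1 / 298.257223563
UTM_K0 <- 0.9996
UTM_FE <- 500000

utm_central_meridian <- function(zone) (zone - 1) * 6 - 180 + 3

#' Project geographic coordinates to UTM
#'
#' Forward transverse Mercator projection (WGS84). Zone 4 covers the central
#' North Pacific and is the package default. Longitudes more than about 10
#' degrees from the zone's central meridian trigger a warning: the series
#' degrades out of zone.
#'
#' @param lat,lon Coordinates in degrees (vectorised).
#' @param zone UTM zone number (default 4).
#' @param hemisphere "N" or "S" (controls the false northing).
#' @return Tibble with `x`, `y` in metres.
#' @export
latlon_to_utm <- function(lat, lon, zone = 4, hemisphere = "N") {
  if (any(abs(lat) > 84)) abort("latlon_to_utm: latitude beyond +/-84 degrees")
  lon0 <- utm_central_meridian(zone)
  dlon <- (lon - lon0 + 180) %% 360 - 180
  if (any(abs(dlon) > 10))
    warn(sprintf("latlon_to_utm: longitude(s) > 10 deg from zone %d central meridian",
                 zone))
  e2 <- WGS84_F * (2 - WGS84_F)
  ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  lam <- dlon * pi / 180
  N <- WGS84_A / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- lam * cos(phi)
  M <- WGS84_A * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
    (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
    (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
    (35 * e2^3 / 3072) * sin(6 * phi))
  x <- UTM_FE + UTM_K0 * N *
    (A + (1 - T + C) * A^3 / 6 +
       (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120)
  y <- UTM_K0 * (M + N * tan(phi) *
                   (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                      (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (hemisphere == "S") y <- y + 1e7
  tibble(x = x, y = y)
}

#' Inverse UTM projection
#'
#' @param x,y UTM easting/northing in metres.
#' @inheritParams latlon_to_utm
#' @return Tibble with `lat`, `lon` in degrees.
#' @export
utm_to_latlon <- function(x, y, zone = 4, hemisphere = "N") {
  if (hemisphere == "S") y <- y - 1e7
  e2 <- WGS84_F * (2 - WGS84_F)
  ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  M <- y / UTM_K0
  mu <- M / (WGS84_A * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  N1 <- WGS84_A / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- WGS84_A * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  T1 <- tan(phi1)^2
  C1 <- ep2 * cos(phi1)^2
  D <- (x - UTM_FE) / (N1 * UTM_K0)
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) *
       D^6 / 720)
  lam <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
            (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) *
            D^5 / 120) / cos(phi1)
  tibble(lat = phi * 180 / pi,
         lon = utm_central_meridian(zone) + lam * 180 / pi)
}

#' Project a filtered track to planar UTM coordinates
#'
#' Adds `x`, `y` columns (metres) for the retained fixes of a track table,
#' the input expected by the local-convex-hull home-range functions.
#'
#' @param track Tibble with `lat`, `lon` (and optionally `retained`).
#' @param zone UTM zone (default 4).
#' @return The track with `x`, `y` columns appended.
#' @export
project_to_planar <- function(track, zone = 4) {
  xy <- latlon_to_utm(track$lat, track$lon, zone = zone)
  mutate(track, x = xy$x, y = xy$y)
}
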