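## Low-precision solar and lunar ephemeris.
##
## Standard astronomical approximations (Astronomical Almanac / van
## Flandern & Pulkkinen style truncated series): geocentric ecliptic
## coordinates of the sun and moon from days since J2000, converted to
## equatorial coordinates, local sun altitude via the hour angle, and lunar
## illuminated fraction from the sun-moon phase angle.  Accuracy is a few
## tenths of a degree in altitude and ~0.01 in illuminated fraction, ample
## for covariates on an hourly grid.

RAD <- pi / 180
OBLIQUITY <- 23.4397 * RAD          # obliquity of the ecliptic, J2000

#' @noRd
daysSinceJ2000 <- function(t) {
  as.numeric(t, units = "secs") / 86400 - 10957.5
}

## Geocentric equatorial coordinates of the sun: list(ra, dec, dist_km)
#' @noRd
sunCoords <- function(d) {
  M <- RAD * (357.5291 + 0.98560028 * d)                  # mean anomaly
  C <- RAD * (1.9148 * sin(M) + 0.02 * sin(2 * M) + 0.0003 * sin(3 * M))
  L <- M + C + RAD * 102.9372 + pi                        # ecliptic longitude
  list(ra = atan2(sin(L) * cos(OBLIQUITY), cos(L)),
       dec = asin(sin(L) * sin(OBLIQUITY)),
       dist = 149598000)
}

## Geocentric equatorial coordinates of the moon: list(ra, dec, dist_km)
#' @noRd
moonCoords <- function(d) {
  L <- RAD * (218.316 + 13.176396 * d)   # mean longitude
  M <- RAD * (134.963 + 13.064993 * d)   # mean anomaly
  F <- RAD * (93.272 + 13.229350 * d)    # mean distance (argument of latitude)
  lon <- L + RAD * 6.289 * sin(M)
  lat <- RAD * 5.128 * sin(F)
  dist <- 385001 - 20905 * cos(M)
  list(ra = atan2(sin(lon) * cos(OBLIQUITY) - tan(lat) * sin(OBLIQUITY),
                  cos(lon)),
       dec = asin(sin(lat) * cos(OBLIQUITY) +
                  cos(lat) * sin(OBLIQUITY) * sin(lon)),
       dist = dist)
}

#' Sun altitude above the horizon
#'
#' @param times POSIXct vector.
#' @param lat,lon observer latitude/longitude in decimal degrees (east
#'   positive).
#' @return altitude in degrees.
#' @export
sunAltitude <- function(times, lat, lon) {
  stopIfNot(abs(lat) <= 90, "latitude must be in [-90, 90]")
  stopIfNot(abs(lon) <= 180, "longitude must be in [-180, 180]")
  d <- daysSinceJ2000(times)
  s <- sunCoords(d)
  lw <- -lon * RAD
  phi <- lat * RAD
  theta <- RAD * (280.16 + 360.9856235 * d) - lw        # sidereal time
  H <- theta - s$ra                                     # hour angle
  asin(sin(phi) * sin(s$dec) + cos(phi) * cos(s$dec) * cos(H)) / RAD
}

#' Lunar illuminated fraction
#'
#' Fraction of the moon's disc illuminated, from the sun-moon phase angle:
#' 0 at new moon, 1 at full moon.
#'
#' @param times POSIXct vector.
#' @return numeric vector in \[0, 1\].
#' @export
lunarFraction <- function(times) {
  d <- daysSinceJ2000(times)
  s <- sunCoords(d)
  m <- moonCoords(d)
  # geocentric elongation of the moon from the sun
  phi <- acos(pmin(1, pmax(-1,
    sin(s$dec) * sin(m$dec) +
      cos(s$dec) * cos(m$dec) * cos(s$ra - m$ra))))
  # phase angle, correcting for finite sun-moon distances
  inc <- atan2(s$dist * sin(phi), m$dist - s$dist * cos(phi))
  (1 + cos(inc)) / 2
}

#' Hourly covariate table for temporal occurrence models
#'
#' Builds the covariates used by the temporal models: hour of day and day of
#' year in local standard time, calendar year, day-of-year expressed as a
#' fraction of that year's length (so leap years align on the annual cycle),
#' lunar illuminated fraction, and sun altitude.  A user-supplied table of
#' precomputed values (e.g. from a high-precision ephemeris) overrides the
#' built-in approximations.
#'
#' @param times POSIXct vector (typically hour starts).
#' @param lat,lon site coordinates in decimal degrees.
#' @param override optional data.frame with column `time` (POSIXct or
#'   ISO-8601 character) and any of `lunar_fraction`, `sun_altitude`; rows
#'   are matched by timestamp and replace computed values.
#' @return data.frame with columns `time`, `hour_of_day`, `day_of_year`,
#'   `year`, `doy_frac` (day of year as a fraction of the year's length),
#'   `year_frac` (decimal year), `lunar_fraction`, `sun_altitude`.
#' @examples
#' h <- seq(parsePamTime("2015-06-01T00:00:00"), by = 3600, length.out = 48)
#' cov <- computeEphemeris(h, lat = 19.6, lon = -156.0)
#' range(cov$lunar_fraction)
#' @export
computeEphemeris <- function(times, lat, lon, override = NULL) {
  stopIfNot(abs(lat) <= 90, "latitude must be in [-90, 90]")
  stopIfNot(abs(lon) <= 180, "longitude must be in [-180, 180]")
  lt <- as.POSIXlt(times, tz = PAM_TZ)
  out <- data.frame(
    time = as.POSIXct(lt),
    hour_of_day = lt$hour + lt$min / 60 + lt$sec / 3600,
    day_of_year = lt$yday + 1L,
    year = lt$year + 1900L)
  out$doy_frac <- (out$day_of_year - 1) / daysInYear(out$year)
  out$year_frac <- out$year + out$doy_frac
  out$lunar_fraction <- lunarFraction(out$time)
  out$sun_altitude <- sunAltitude(out$time, lat, lon)
  if (!is.null(override) && nrow(override)) {
    ot <- override$time
    if (is.character(ot)) ot <- parsePamTime(ot)
    idx <- match(as.numeric(out$time), as.numeric(ot))
    hit <- !is.na(idx)
    for (col in intersect(c("lunar_fraction", "sun_altitude"),
                          names(override)))
      out[[col]][hit] <- override[[col]][idx[hit]]
  }
  out
}
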