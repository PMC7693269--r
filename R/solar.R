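# NOAA-style solar position. Angles in degrees, times in UTC.
# Longitude convention: positive east. Day-of-year is 1-based with leap days
# dropped, so every year has 365 days (see doy_from_time()).

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Fractional year (radians) from a 365-day doy and fractional UTC hour.
.solar_gamma <- function(doy, hour) {
  2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
}

#' Equation of time
#'
#' Difference between apparent and mean solar time, in minutes, from the
#' NOAA low-precision series expansion.
#'
#' @param doy Day of year (1--365), leap days dropped.
#' @param hour Fractional UTC hour (default 12).
#' @return Minutes (apparent minus mean solar time).
#' @export
equation_of_time <- function(doy, hour = 12) {
  g <- .solar_gamma(doy, hour)
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

#' Solar declination
#'
#' @inheritParams equation_of_time
#' @return Declination in degrees.
#' @export
solar_declination <- function(doy, hour = 12) {
  g <- .solar_gamma(doy, hour)
  .rad2deg(
    0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
      0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
      0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  )
}

#' Solar elevation angle
#'
#' Elevation of the sun above the horizon for a given instant and position,
#' from the NOAA solar position formulas (no atmospheric refraction).
#'
#' @param doy Day of year (1--365).
#' @param hour Fractional UTC hour.
#' @param latitude,longitude Degrees; longitude positive east.
#' @return Elevation in degrees.
#' @export
solar_elevation <- function(doy, hour, latitude, longitude) {
  eqt <- equation_of_time(doy, hour)
  decl <- .deg2rad(solar_declination(doy, hour))
  # true solar time in minutes
  tst <- (hour * 60 + eqt + 4 * longitude) %% 1440
  ha <- .deg2rad(tst / 4 - 180)
  lat <- .deg2rad(latitude)
  cos_zen <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  90 - .rad2deg(acos(pmin(1, pmax(-1, cos_zen))))
}

#' Solar noon, sunrise and sunset (UTC)
#'
#' Closed-form twilight times from the sunrise equation for an arbitrary
#' solar zenith angle. A zenith of 90.833 degrees gives conventional
#' sunrise/sunset; 96 gives civil twilight.
#'
#' @inheritParams solar_elevation
#' @param zenith Solar zenith angle defining "twilight", degrees.
#' @return A tibble with `noon_utc`, `rise_utc`, `set_utc` (fractional UTC
#'   hours; `NA` for polar day/night) and `day_length_h`.
#' @export
twilight_times <- function(doy, latitude, longitude, zenith = 96) {
  eqt <- equation_of_time(doy)
  decl <- .deg2rad(solar_declination(doy))
  lat <- .deg2rad(latitude)
  cos_ha <- (cos(.deg2rad(zenith)) - sin(lat) * sin(decl)) /
    (cos(lat) * cos(decl))
  ha <- .rad2deg(acos(pmin(1, pmax(-1, cos_ha)))) # degrees
  polar <- abs(cos_ha) > 1
  noon <- (720 - 4 * longitude - eqt) / 60
  rise <- noon - ha * 4 / 60
  set <- noon + ha * 4 / 60
  rise[polar] <- NA_real_
  set[polar] <- NA_real_
  tibble::tibble(
    doy = doy,
    noon_utc = noon,
    rise_utc = rise,
    set_utc = set,
    day_length_h = ifelse(polar, ifelse(cos_ha < -1, 24, 0), ha * 8 / 60)
  )
}

# Great-circle interpolation between two points; frac in [0, 1].
# Returns list(lat, lon) in degrees.
.gc_interp <- function(lat1, lon1, lat2, lon2, frac) {
  p1 <- .deg2rad(c(lat1, lon1))
  p2 <- .deg2rad(c(lat2, lon2))
  xyz <- function(p) c(cos(p[1]) * cos(p[2]), cos(p[1]) * sin(p[2]), sin(p[1]))
  a <- xyz(p1)
  b <- xyz(p2)
  omega <- acos(pmin(1, pmax(-1, sum(a * b))))
  if (omega < 1e-12) {
    return(list(lat = rep(lat1, length(frac)), lon = rep(lon1, length(frac))))
  }
  s1 <- sin((1 - frac) * omega) / sin(omega)
  s2 <- sin(frac * omega) / sin(omega)
  x <- s1 * a[1] + s2 * b[1]
  y <- s1 * a[2] + s2 * b[2]
  z <- s1 * a[3] + s2 * b[3]
  list(lat = .rad2deg(asin(pmin(1, pmax(-1, z)))), lon = .rad2deg(atan2(y, x)))
}

#' Day of year with leap days dropped
#'
#' Maps calendar dates (or POSIXct) to a 1--365 day-of-year index. Feb 29 is
#' collapsed onto Feb 28 so that multi-year climatologies align.
#'
#' @param x A `Date` or `POSIXct` vector.
#' @return Integer day of year in 1--365.
#' @export
doy_from_time <- function(x) {
  d <- as.POSIXlt(x, tz = "UTC")
  doy <- d$yday + 1L
  leap <- (d$year + 1900) %% 4 == 0 &
    ((d$year + 1900) %% 100 != 0 | (d$year + 1900) %% 400 == 0)
  # after Feb 29 in a leap year, shift back one so the year has 365 days
  doy[leap & doy > 59] <- doy[leap & doy > 59] - 1L
  pmin(doy, 365L)
}
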