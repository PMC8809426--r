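#' Solar elevation angle
#'
#' Computes the elevation of the sun above the horizon, in degrees, using
#' the NOAA solar-position approximation (low-accuracy ephemeris: geometric
#' mean longitude/anomaly, equation of center, obliquity with nutation
#' correction, and the equation of time). Atmospheric refraction is not
#' applied; it matters only within ~0.6 degrees of the horizon and is
#' irrelevant at the astronomical-twilight threshold of -18 degrees.
#' Accuracy is well within 0.5 degrees over 1900--2100.
#'
#' @param latitude,longitude decimal degrees; longitude positive east.
#' @param time POSIXct (any timezone; converted to UTC internally).
#' @return numeric vector of solar elevations in degrees.
#' @examples
#' # local noon in midsummer at a mid-northern latitude is daylight
#' solar_elevation(43.48, -110.76,
#'   as.POSIXct("2018-06-21 12:00:00", tz = "US/Mountain"))
#' @export
solar_elevation <- function(latitude, longitude, time) {
  if (any(is.na(latitude)) || any(is.na(longitude))) {
    stop_config("solar_elevation: missing coordinates")
  }
  if (any(abs(latitude) > 90) || any(abs(longitude) > 180)) {
    stop_input("solar_elevation: coordinates out of range")
  }
  rad <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ec <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C  <- sin(M * rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
        sin(2 * M * rad) * (0.019993 - 0.000101 * jc) +
        sin(3 * M * rad) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * rad)
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * rad)
  decl <- asin(sin(eps * rad) * sin(lambda * rad))

  y <- tan(eps * rad / 2)^2
  eqtime <- 4 / rad * (y * sin(2 * L0 * rad) - 2 * ec * sin(M * rad) +
    4 * ec * y * sin(M * rad) * cos(2 * L0 * rad) -
    0.5 * y^2 * sin(4 * L0 * rad) - 1.25 * ec^2 * sin(2 * M * rad))

  mins_utc <- (jd + 0.5 - floor(jd + 0.5)) * 1440
  tst <- (mins_utc + eqtime + 4 * longitude) %% 1440
  ha <- tst / 4 - 180
  elev <- asin(sin(latitude * rad) * sin(decl) +
               cos(latitude * rad) * cos(decl) * cos(ha * rad))
  elev / rad
}

#' Is it astronomical night?
#'
#' @param latitude,longitude decimal degrees.
#' @param time POSIXct.
#' @param threshold_deg solar elevation below which it is "night";
#'   -18 degrees (astronomical twilight) by default.
#' @return logical vector.
#' @export
is_astronomical_night <- function(latitude, longitude, time, threshold_deg = -18) {
  solar_elevation(latitude, longitude, time) < threshold_deg
}
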