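# Solar geometry: extraterrestrial radiation and daylength from latitude and
# day of year. Declination and the Earth-Sun distance factor use the Spencer
# (1971) Fourier series (accurate to a few hundredths of a degree, vs up to
# ~0.17 h of daylength error at mid-latitudes for the common single-harmonic
# approximation); the radiation integral is the standard extraterrestrial
# form. Daylength is geometric (centre of sun at the horizon, no refraction).

GSC_MJ_M2_MIN <- 0.0820  # solar constant, MJ m-2 min-1

# Spencer (1971) series: solar declination (radians) and eccentricity
# correction factor E0 = (r0/r)^2 as functions of the day angle
.spencer <- function(doy) {
  g <- 2 * pi * (doy - 1) / 365
  list(
    decl = 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
      0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
      0.002697 * cos(3 * g) + 0.001480 * sin(3 * g),
    e0 = 1.000110 + 0.034221 * cos(g) + 0.001280 * sin(g) +
      0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)
  )
}

#' Solar geometry for one or more days of the year
#'
#' Computes solar declination, extraterrestrial (potential) solar radiation
#' and daylength for a latitude and day of year. Declination \eqn{\delta}
#' and the eccentricity correction \eqn{E_0} come from the Spencer (1971)
#' Fourier series; then with sunset hour angle
#' \eqn{\omega_s = \arccos(-\tan\phi \tan\delta)}, radiation is
#' \eqn{R_a = (24 \cdot 60/\pi) G_{sc} E_0 (\omega_s \sin\phi
#' \sin\delta + \cos\phi \cos\delta \sin\omega_s)} with
#' \eqn{G_{sc} = 0.0820} MJ m-2 min-1, and daylength is
#' \eqn{N = (24/\pi)\omega_s}. The day angle always uses a 365-day year,
#' also in leap years; the difference is far below model precision.
#'
#' @param latitude Latitude in decimal degrees, positive north. Must satisfy
#'   \code{abs(latitude) <= 66.5}: polar day/night is not handled.
#' @param doy Day of year, integer in 1..366. May be a vector.
#' @return A data frame with one row per \code{doy} and columns \code{doy},
#'   \code{latitude}, \code{declination} (radians), \code{ra}
#'   (MJ m-2 day-1) and \code{daylength} (hours).
#' @examples
#' solar_day(39.6, 172)   # near the summer solstice
#' solar_day(0, c(80, 172, 355))$daylength  # ~12 h all year at the equator
#' @export
solar_day <- function(latitude, doy) {
  if (!is.numeric(latitude) || length(latitude) != 1L || !is.finite(latitude)) {
    stop("latitude must be a single finite number (decimal degrees)")
  }
  if (abs(latitude) > 66.5) {
    stop("unsupported latitude ", latitude,
         ": polar day/night (|latitude| > 66.5) is not handled")
  }
  doy <- as.integer(doy)
  if (length(doy) < 1L || anyNA(doy) || any(doy < 1L | doy > 366L)) {
    stop("doy must be integer(s) in 1..366")
  }
  phi <- latitude * pi / 180
  sp <- .spencer(doy)
  decl <- sp$decl
  # |lat| <= 66.5 keeps the argument in (-1, 1); clamp guards rounding only
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
  ra <- (24 * 60 / pi) * GSC_MJ_M2_MIN * sp$e0 *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  data.frame(
    doy = doy,
    latitude = latitude,
    declination = decl,
    ra = pmax(0, ra),
    daylength = 24 / pi * ws
  )
}

#' Day of year of the summer solstice
#'
#' Used to split the year into the ascending-daylength (spring) and
#' descending-daylength (late-summer) phases of the daylength growth
#' response. Fixed calendar convention: doy 172 in common years, 173 in
#' leap years.
#'
#' @param year Calendar year (integer).
#' @return Integer day of year.
#' @export
solstice_doy <- function(year) {
  ifelse(is_leap_year(year), 173L, 172L)
}

#' @rdname solstice_doy
#' @export
is_leap_year <- function(year) {
  year <- as.integer(year)
  (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
}

#' Solar table for a whole year
#'
#' Convenience wrapper returning \code{\link{solar_day}} for every day of a
#' calendar year at one latitude.
#'
#' @inheritParams solar_day
#' @param year Calendar year (controls 365 vs 366 days).
#' @return Data frame as in \code{\link{solar_day}}, one row per day.
#' @export
solar_table <- function(latitude, year) {
  n <- if (is_leap_year(year)) 366L else 365L
  solar_day(latitude, seq_len(n))
}
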