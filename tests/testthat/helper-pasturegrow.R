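# Shared fixtures and independent oracles for the test suite.

# constant-weather series: every day the same temperatures and rainfall
constant_weather <- function(year = 2001, t_min = 15, t_max = 15,
                             precip = 10) {
  n <- if (pasturegrow::is_leap_year(year)) 366L else 365L
  pasturegrow::weather_series(data.frame(
    year = year, doy = seq_len(n), t_min = t_min, t_max = t_max,
    precip = precip
  ), site = "constant")
}

# Independent solar oracle: NOAA-style (Meeus) solar declination from the
# Julian century, with geometric daylength from the sunset hour angle.
# Shares no code or series coefficients with the package implementation.
noaa_daylength <- function(latitude, year, doy) {
  jd <- as.numeric(as.Date(paste0(year, "-01-01")) + (doy - 1)) +
    2440587.5 + 0.5
  jc <- (jd - 2451545) / 36525
  l0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  m <- (357.52911 + jc * (35999.05029 - 0.0001537 * jc)) * pi / 180
  c_eq <- sin(m) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m) * (0.019993 - 0.000101 * jc) + sin(3 * m) * 0.000289
  app <- l0 + c_eq - 0.00569 -
    0.00478 * sin((125.04 - 1934.136 * jc) * pi / 180)
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos((125.04 - 1934.136 * jc) * pi / 180)
  decl <- asin(sin(eps * pi / 180) * sin(app * pi / 180))
  phi <- latitude * pi / 180
  24 / pi * acos(pmin(1, pmax(-1, -tan(phi) * tan(decl))))
}

# closed-form simple linear regression (independent of stats::lm)
closed_form_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  fitted <- a + b * x
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  list(intercept = a, slope = b, fitted = fitted,
       r2 = 1 - sse / sst, sd_reg = sqrt(sse / (n - 2)),
       aape = 100 / n * sum(abs(y - fitted) / abs(y)))
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
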