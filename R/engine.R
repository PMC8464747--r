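# The daily simulation loop: solar geometry -> pan evaporation ->
# evapotranspiration -> soil water balance -> thermal-time accumulation and
# growth initiation -> the four relative growth rate factors -> their product
# rgr_env and its season total cum_rgr_env.

DAILY_STATE_COLUMNS <- c(
  "year", "doy", "t_mean", "ra", "daylength", "pan", "et", "asw", "tsum",
  "growth_active", "rgr_asw", "rgr_temp", "rgr_dl", "rgr_sbio", "rgr_env",
  "cum_rgr_env"
)

#' Site configuration
#'
#' Everything the simulator needs beyond the weather: latitude, the soil's
#' maximum plant-available water, the plant response parameters and the
#' evapotranspiration parameters. A plant-type \code{et_pan_fraction}
#' override (as in \code{\link{c4_defaults}}) takes precedence over the
#' value in \code{et}.
#'
#' @param latitude Decimal degrees, positive north; \code{abs(latitude)}
#'   must be at most 66.5.
#' @param asw_max Maximum plant-available soil water, mm (> 0). Soil-survey
#'   values quoted in inches can be passed via \code{asw_max_inches}.
#' @param plant A \code{\link{plant_params}} object (default
#'   \code{\link{c3_defaults}()}).
#' @param et An \code{\link{et_params}} object.
#' @param asw_max_inches Alternative to \code{asw_max}: plant-available
#'   water in inches, converted at 25.4 mm/inch.
#' @return An object of class \code{site_config}.
#' @examples
#' site_config(latitude = 39.6, asw_max_inches = 9)   # 228.6 mm
#' @export
site_config <- function(latitude, asw_max = NULL, plant = c3_defaults(),
                        et = et_params(), asw_max_inches = NULL) {
  if (abs(latitude) > 66.5) {
    stop("unsupported latitude ", latitude, " (|latitude| must be <= 66.5)")
  }
  if (is.null(asw_max)) {
    if (is.null(asw_max_inches)) stop("one of asw_max or asw_max_inches is required")
    asw_max <- asw_max_inches * 25.4
  }
  if (asw_max <= 0) stop("asw_max must be > 0")
  stopifnot(inherits(plant, "plant_params"), inherits(et, "et_params"))
  if (!is.null(plant$et_pan_fraction)) {
    et$et_pan_fraction <- plant$et_pan_fraction
  }
  structure(list(latitude = latitude, asw_max = asw_max, plant = plant,
                 et = et),
            class = "site_config")
}

#' Accumulate thermal time
#'
#' Thermal time (Tsum) is the running sum of positive daily mean
#' temperatures from 1 January; negative daily means are ignored, never
#' subtracted. Growth initiates the day Tsum reaches the plant's
#' \code{tsum_start} threshold (280 or 300 degree C days for cool-season
#' grass, site-dependent).
#'
#' @param prev_tsum Accumulated thermal time before today, degree C days
#'   (>= 0).
#' @param t_mean Today's mean air temperature, degrees C.
#' @return Updated thermal time.
#' @examples
#' accumulate_tsum(100, 7.5)  # 107.5
#' accumulate_tsum(100, -4)   # 100
#' @export
accumulate_tsum <- function(prev_tsum, t_mean) {
  if (any(prev_tsum < 0)) stop("prev_tsum must be >= 0")
  prev_tsum + pmax(0, t_mean)
}

# one calendar year (or contiguous partial year); asw0 is the 1 January (or
# first-day) store in mm; returns list(states, asw_end)
.simulate_one_year <- function(records, cfg) {
  n <- nrow(records)
  year <- records$year[1]
  sol <- solar_day(cfg$latitude, records$doy)
  t_mean <- (records$t_min + records$t_max) / 2
  t_range <- records$t_max - records$t_min
  pan <- pan_evaporation(sol$ra, t_mean, t_range, cfg$et)
  et <- evapotranspiration(pan, cfg$et)
  phase <- ifelse(records$doy <= solstice_doy(year), "ascending", "descending")

  asw <- numeric(n)
  tsum <- cumsum(pmax(0, t_mean))
  a <- attr(records, "asw0")
  for (i in seq_len(n)) {
    a <- min(cfg$asw_max, max(0, a + records$precip[i] - et[i]))
    asw[i] <- a
  }
  active <- tsum >= cfg$plant$tsum_start
  f_asw <- rgr_asw(asw, cfg$asw_max)
  f_temp <- rgr_temp(t_mean, cfg$plant)
  f_dl <- rgr_daylength(sol$daylength, phase, cfg$plant)
  f_sbio <- rgr_sbio(asw, cfg$asw_max)
  rgr_env <- ifelse(active, f_asw * f_temp * f_dl * f_sbio, 0)

  states <- data.frame(
    year = records$year, doy = records$doy, t_mean = t_mean, ra = sol$ra,
    daylength = sol$daylength, pan = pan, et = et, asw = asw, tsum = tsum,
    growth_active = active, rgr_asw = f_asw, rgr_temp = f_temp,
    rgr_dl = f_dl, rgr_sbio = f_sbio, rgr_env = rgr_env,
    cum_rgr_env = cumsum(rgr_env)
  )
  list(states = states, asw_end = asw[n])
}

#' Simulate pasture growing conditions over a weather series
#'
#' Runs the daily model over every day of the series. Each day the model
#' computes solar radiation and daylength from latitude and day of year,
#' pan evaporation and plant evapotranspiration, the soil water balance
#' (previous store + precipitation - evapotranspiration, clamped to
#' \code{[0, asw_max]}), thermal time, and the four relative growth rate
#' factors (soil water, temperature, daylength, soil biology). The daily
#' environmental relative growth rate \code{rgr_env} is the product of the
#' four factors once growth has initiated (thermal time at or above
#' \code{tsum_start}) and 0 before; \code{cum_rgr_env} is its running sum
#' over the year.
#'
#' Thermal time and \code{cum_rgr_env} reset every 1 January; once
#' initiated, growth stays active for the rest of the calendar year (the
#' temperature and daylength factors shut it down in autumn). Soil water
#' carries across year boundaries. On the first simulated day the store
#' starts at \code{asw_init_frac * asw_max} (default full: humid temperate
#' winters recharge the soil to capacity). Evapotranspiration is withdrawn
#' every day of the year, also before growth initiation. The run is fully
#' deterministic.
#'
#' @param weather A \code{\link{weather_series}} (multi-year allowed; years
#'   must be contiguous).
#' @param cfg A \code{\link{site_config}}.
#' @param asw_init_frac Initial soil water store as a fraction of
#'   \code{asw_max}, in \code{[0, 1]}.
#' @return Data frame with one row per day and columns
#'   \code{year, doy, t_mean, ra, daylength, pan, et, asw, tsum,
#'   growth_active, rgr_asw, rgr_temp, rgr_dl, rgr_sbio, rgr_env,
#'   cum_rgr_env}.
#' @seealso \code{\link{simulate_year}}, \code{\link{annual_totals}}
#' @export
simulate_growth <- function(weather, cfg, asw_init_frac = 1) {
  stopifnot(inherits(weather, "weather_series"), inherits(cfg, "site_config"))
  if (asw_init_frac < 0 || asw_init_frac > 1) {
    stop("asw_init_frac must lie in [0, 1]")
  }
  rec <- weather$records
  if (nrow(rec) == 0L) stop("cannot simulate an empty weather series")
  out <- vector("list", length(unique(rec$year)))
  asw0 <- asw_init_frac * cfg$asw_max
  i <- 0L
  for (yr in sort(unique(rec$year))) {
    i <- i + 1L
    ry <- rec[rec$year == yr, , drop = FALSE]
    attr(ry, "asw0") <- asw0
    res <- .simulate_one_year(ry, cfg)
    out[[i]] <- res$states
    asw0 <- res$asw_end
  }
  states <- do.call(rbind, out)
  rownames(states) <- NULL
  states
}

#' Simulate a single year
#'
#' Convenience wrapper over \code{\link{simulate_growth}} for one calendar
#' year of a series.
#'
#' @inheritParams simulate_growth
#' @param year Which calendar year of the series to simulate.
#' @return Daily-state data frame for that year.
#' @export
simulate_year <- function(weather, cfg, year = NULL, asw_init_frac = 1) {
  stopifnot(inherits(weather, "weather_series"))
  rec <- weather$records
  if (is.null(year)) {
    if (length(unique(rec$year)) != 1L) {
      stop("series spans several years; pass `year`")
    }
    year <- rec$year[1]
  }
  rec <- rec[rec$year == year, , drop = FALSE]
  if (nrow(rec) == 0L) stop("year ", year, " not present in the weather series")
  simulate_growth(weather_series(rec, site = weather$site), cfg,
                  asw_init_frac = asw_init_frac)
}

#' End-of-year totals of cumulative environmental growth rate
#'
#' @param states Daily-state data frame from \code{\link{simulate_growth}}.
#' @return Data frame with columns \code{year}, \code{cum_rgr_env} (the last
#'   day's running total), \code{n_days} and \code{growth_start_doy} (first
#'   growth-active day, NA if growth never initiated).
#' @export
annual_totals <- function(states) {
  years <- sort(unique(states$year))
  do.call(rbind, lapply(years, function(yr) {
    s <- states[states$year == yr, , drop = FALSE]
    act <- which(s$growth_active)
    data.frame(year = yr, cum_rgr_env = s$cum_rgr_env[nrow(s)],
               n_days = nrow(s),
               growth_start_doy = if (length(act)) s$doy[act[1]] else NA_integer_)
  }))
}
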