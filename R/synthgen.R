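# Seeded synthetic data: daily weather for a humid temperate mid-latitude
# climate (sinusoidal annual temperature + noise, intermittent rainfall with
# a controllable summer-drought window) and observation tables with a known
# linear observed ~ modelled relation. All randomness flows from the
# explicit seed in the spec; the caller's RNG state is left untouched.

# run expr under a private RNG stream seeded with `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic climate specification
#'
#' Defaults describe a humid temperate mid-latitude (Allegheny Plateau-like)
#' climate: annual mean near 11 degrees C with an 11.5 degree seasonal
#' amplitude (January mean about -0.5, July about 22.5), an 11 degree mean
#' diurnal range, about a third of days wet, and roughly 1100 mm annual
#' rainfall. The optional drought window scales rainfall amounts (after
#' drawing wet days) over a day-of-year range, so a baseline and a drought
#' run with the same seed share wet days exactly.
#'
#' @param latitude Site latitude, decimal degrees north.
#' @param annual_mean_temp Annual mean temperature, degrees C.
#' @param seasonal_amplitude Half the summer-winter range of daily means,
#'   degrees C; the coldest day is near 15 January.
#' @param diurnal_range_mean Mean daily \code{t_max - t_min}, degrees C.
#' @param temp_noise_sd Day-to-day standard deviation of the mean
#'   temperature about the sinusoid, degrees C.
#' @param wet_day_prob Probability a day is wet; scalar or length-12 vector
#'   by month.
#' @param rain_per_wet_day_mm Mean rainfall on a wet day, mm (exponential
#'   amounts).
#' @param wet_persistence Optional probability in \code{[0, 1)} adding
#'   two-state Markov persistence of wet/dry runs; 0 (the default) gives
#'   independent days at the specified wet-day probability.
#' @param drought_window Integer day-of-year range \code{c(from, to)} over
#'   which rainfall amounts are multiplied, or \code{NULL}.
#' @param drought_multiplier Multiplier (>= 0) applied to rainfall amounts
#'   inside the drought window.
#' @param temp_delta Uniform temperature offset, degrees C (scenario use).
#' @param seed Integer seed; every draw flows from it.
#' @return An object of class \code{climate_spec}.
#' @export
climate_spec <- function(latitude = 39.6,
                         annual_mean_temp = 11,
                         seasonal_amplitude = 11.5,
                         diurnal_range_mean = 11,
                         temp_noise_sd = 3,
                         wet_day_prob = 0.33,
                         rain_per_wet_day_mm = 9,
                         wet_persistence = 0,
                         drought_window = NULL,
                         drought_multiplier = 1,
                         temp_delta = 0,
                         seed = 1L) {
  if (length(wet_day_prob) == 1L) wet_day_prob <- rep(wet_day_prob, 12L)
  if (length(wet_day_prob) != 12L || any(wet_day_prob < 0 | wet_day_prob > 1)) {
    stop("wet_day_prob must be a scalar or length-12 vector of probabilities")
  }
  if (seasonal_amplitude < 0 || diurnal_range_mean < 0 || temp_noise_sd < 0 ||
      rain_per_wet_day_mm < 0 || drought_multiplier < 0) {
    stop("amplitudes, sds, means and multipliers must be >= 0")
  }
  if (wet_persistence < 0 || wet_persistence >= 1) {
    stop("wet_persistence must lie in [0, 1)")
  }
  if (!is.null(drought_window) &&
      (length(drought_window) != 2L || drought_window[1] > drought_window[2])) {
    stop("drought_window must be c(from_doy, to_doy) with from <= to")
  }
  structure(
    list(latitude = latitude, annual_mean_temp = annual_mean_temp,
         seasonal_amplitude = seasonal_amplitude,
         diurnal_range_mean = diurnal_range_mean,
         temp_noise_sd = temp_noise_sd, wet_day_prob = wet_day_prob,
         rain_per_wet_day_mm = rain_per_wet_day_mm,
         wet_persistence = wet_persistence,
         drought_window = drought_window,
         drought_multiplier = drought_multiplier,
         temp_delta = temp_delta, seed = as.integer(seed)),
    class = "climate_spec"
  )
}

.month_of_doy <- function(year, doy) {
  as.integer(format(.year_doy_to_date(year, doy), "%m"))
}

#' Generate a synthetic daily weather series
#'
#' Daily mean temperature follows a sinusoid (minimum near 15 January) plus
#' Gaussian noise; \code{t_min}/\code{t_max} are placed symmetrically around
#' it at the (noisy, floored at 0) diurnal range. Rainfall occurrence is a
#' Bernoulli draw per day at the monthly wet-day probability (optionally
#' Markov-persistent); wet-day amounts are exponential. A drought window
#' scales amounts after the draws, so runs differing only in the multiplier
#' share wet days. Reproducible: the same spec (same seed) always yields the
#' identical series.
#'
#' @param spec A \code{\link{climate_spec}}.
#' @param years Number of years (>= 1), or a vector of calendar years.
#' @param start_year First calendar year when \code{years} is a count.
#' @return A \code{\link{weather_series}}.
#' @examples
#' wx <- generate_weather(climate_spec(seed = 42), years = 2)
#' @export
generate_weather <- function(spec, years = 1L, start_year = 2001L) {
  stopifnot(inherits(spec, "climate_spec"))
  if (length(years) == 1L && years >= 1L && years == as.integer(years) &&
      years < 1000) {
    years <- seq(start_year, length.out = as.integer(years))
  }
  .with_seed(spec$seed, {
    recs <- lapply(years, function(yr) {
      n <- .days_in_year(yr)
      doy <- seq_len(n)
      base <- spec$annual_mean_temp -
        spec$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365)
      t_mean <- base + stats::rnorm(n, 0, spec$temp_noise_sd) + spec$temp_delta
      rng <- pmax(0.5, stats::rnorm(n, spec$diurnal_range_mean, 2))
      p_wet <- spec$wet_day_prob[.month_of_doy(yr, doy)]
      if (spec$wet_persistence > 0) {
        # two-state chain with stationary prob p_wet and persistence rho:
        # P(wet|wet) = p + rho (1-p), P(wet|dry) = p (1 - rho)
        wet <- logical(n)
        u <- stats::runif(n)
        wet[1] <- u[1] < p_wet[1]
        rho <- spec$wet_persistence
        for (i in 2:n) {
          p <- if (wet[i - 1]) p_wet[i] + rho * (1 - p_wet[i])
               else p_wet[i] * (1 - rho)
          wet[i] <- u[i] < p
        }
      } else {
        wet <- stats::runif(n) < p_wet
      }
      amount <- ifelse(wet, stats::rexp(n, 1 / spec$rain_per_wet_day_mm), 0)
      if (!is.null(spec$drought_window)) {
        inwin <- doy >= spec$drought_window[1] & doy <= spec$drought_window[2]
        amount[inwin] <- amount[inwin] * spec$drought_multiplier
      }
      data.frame(year = yr, doy = doy, t_min = t_mean - rng / 2,
                 t_max = t_mean + rng / 2, precip = amount)
    })
    weather_series(do.call(rbind, recs), site = "synthetic")
  })
}

#' Synthetic observation specification
#'
#' Defines the planted linear relation between relative observed growth
#' (percent of site maximum) and the model's \code{cum_rgr_env}:
#' \code{rel = intercept + slope * cum_rgr_env + year offset +
#' treatment offset + Normal(0, noise_sd)}, floored at 0.
#'
#' @param intercept True intercept, percent.
#' @param slope True slope, percent per unit \code{cum_rgr_env}.
#' @param noise_sd Observation noise standard deviation, percent.
#' @param year_offsets Named numeric vector of additive year effects
#'   (names are calendar years); years not named get 0.
#' @param treatment_offsets Named numeric vector of additive treatment
#'   effects; a single unnamed 0 means one treatment called "control".
#' @param events_per_year Number of observation events per year and
#'   treatment (>= 2), at evenly spaced days of year.
#' @param doy_range Day-of-year range over which events are placed.
#' @param reference_max Site maximum cumulative growth, kg DM/ha, used to
#'   map the percent scale back to kg/ha (\code{cum_fg_obs =
#'   rel * reference_max / 100}); recorded in the output attributes.
#' @param seed Integer seed.
#' @return An object of class \code{obs_spec}.
#' @export
obs_spec <- function(intercept = -3, slope = 0.56, noise_sd = 5,
                     year_offsets = numeric(0),
                     treatment_offsets = c(control = 0),
                     events_per_year = 7L,
                     doy_range = c(120L, 330L),
                     reference_max = 9000,
                     seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (events_per_year < 2L) stop("events_per_year must be >= 2")
  if (reference_max <= 0) stop("reference_max must be > 0")
  structure(
    list(intercept = intercept, slope = slope, noise_sd = noise_sd,
         year_offsets = year_offsets, treatment_offsets = treatment_offsets,
         events_per_year = as.integer(events_per_year),
         doy_range = as.integer(doy_range), reference_max = reference_max,
         seed = as.integer(seed)),
    class = "obs_spec"
  )
}

#' Generate synthetic observation events from a simulation
#'
#' Places \code{events_per_year} events per year and treatment at evenly
#' spaced days of year, computes the planted linear response to the
#' simulated \code{cum_rgr_env} on the percent scale, adds offsets and
#' noise, floors at 0, and converts back to cumulative kg DM/ha via
#' \code{reference_max} (the affine map is recorded in the result's
#' \code{"scale"} attribute so it can be inverted).
#'
#' @param spec An \code{\link{obs_spec}}.
#' @param states Daily-state data frame from \code{\link{simulate_growth}};
#'   must cover every requested year.
#' @param years Years to generate events for (default: all simulated).
#' @return Observation data frame (\code{year, doy, cum_fg_obs, treatment,
#'   replicate}) with attribute \code{"scale" = c(reference_max = ...)}.
#' @export
generate_observations <- function(spec, states, years = NULL) {
  stopifnot(inherits(spec, "obs_spec"))
  sim_years <- sort(unique(states$year))
  if (is.null(years)) years <- sim_years
  missing_years <- setdiff(years, sim_years)
  if (length(missing_years)) {
    stop("requested year(s) not simulated: ",
         paste(missing_years, collapse = ", "))
  }
  doys <- as.integer(round(seq(spec$doy_range[1], spec$doy_range[2],
                               length.out = spec$events_per_year)))
  treatments <- names(spec$treatment_offsets)
  if (is.null(treatments)) treatments <- paste0("t", seq_along(spec$treatment_offsets))
  grid <- expand.grid(doy = doys, year = years, treatment = treatments,
                      stringsAsFactors = FALSE)
  key <- paste(grid$year, grid$doy)
  idx <- match(key, paste(states$year, states$doy))
  if (anyNA(idx)) stop("event day absent from the simulation")
  cum <- states$cum_rgr_env[idx]
  yoff <- spec$year_offsets[as.character(grid$year)]
  yoff[is.na(yoff)] <- 0
  toff <- spec$treatment_offsets[grid$treatment]
  ev <- .with_seed(spec$seed, {
    rel <- spec$intercept + spec$slope * cum + as.numeric(yoff) +
      as.numeric(toff) + stats::rnorm(nrow(grid), 0, spec$noise_sd)
    rel <- pmax(0, rel)
    data.frame(year = grid$year, doy = grid$doy,
               cum_fg_obs = rel * spec$reference_max / 100,
               treatment = grid$treatment, replicate = "r1",
               stringsAsFactors = FALSE)
  })
  ev <- ev[order(ev$treatment, ev$replicate, ev$year, ev$doy), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "scale") <- c(reference_max = spec$reference_max)
  class(ev) <- c("observation_events", "data.frame")
  ev
}

#' Write an observation table to CSV
#'
#' @param events Observation data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_observations <- function(events, path) {
  out <- data.frame(year = events$year, doy = events$doy,
                    cum_fg_obs_kg_ha = events$cum_fg_obs,
                    treatment = events$treatment,
                    replicate = events$replicate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
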