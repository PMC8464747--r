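# Soil water: pan-evaporation surrogate, plant evapotranspiration as a
# fraction of pan evaporation, and the plant-available soil water (ASW)
# bucket with its relative-growth-rate ramps.

#' Evapotranspiration parameters
#'
#' Bundles the pan-evaporation strategy with the fraction converting pan
#' evaporation to plant evapotranspiration.
#'
#' Two strategies are provided. \code{"hargreaves"} (the default) is a
#' Hargreaves-Samani-style surrogate,
#' \eqn{pan = 0.0023 (R_a/2.45)(t_{mean} + 17.8)\sqrt{t_{range}}},
#' with \eqn{R_a/2.45} the extraterrestrial radiation expressed as mm/day of
#' water equivalent. \code{"linear"} is a generic regression
#' \eqn{pan = b_0 + b_1 R_a + b_2 t_{mean} + b_3 t_{range}} so that a locally
#' fitted pan-evaporation regression on the same three predictors can be
#' dropped in via \code{coefficients}. Both strategies floor the result at 0.
#'
#' @param pan_model Strategy name, \code{"hargreaves"} or \code{"linear"}.
#' @param et_pan_fraction Plant evapotranspiration as a fraction of pan
#'   evaporation, in (0, 1]. Default 0.80 (conventional cool-season value
#'   for humid Northeast-US pasture); warm-season forages use 0.75.
#' @param coefficients Named numeric vector of strategy coefficients. For
#'   \code{"hargreaves"}: \code{k} (default 0.0023). For \code{"linear"}:
#'   \code{b0,b1,b2,b3}.
#' @return An object of class \code{et_params}.
#' @examples
#' et_params()
#' et_params("linear", coefficients = c(b0 = -1, b1 = 0.1, b2 = 0.05, b3 = 0.1))
#' @export
et_params <- function(pan_model = "hargreaves", et_pan_fraction = 0.80,
                      coefficients = NULL) {
  if (!pan_model %in% c("hargreaves", "linear")) {
    stop("unknown pan-evaporation strategy: '", pan_model,
         "' (available: hargreaves, linear)")
  }
  if (!is.numeric(et_pan_fraction) || length(et_pan_fraction) != 1L ||
      et_pan_fraction <= 0 || et_pan_fraction > 1) {
    stop("et_pan_fraction must be in (0, 1]")
  }
  default_coef <- switch(pan_model,
    hargreaves = c(k = 0.0023),
    linear = c(b0 = 0, b1 = 0.1, b2 = 0, b3 = 0)
  )
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) || anyNA(names(coefficients))) {
      stop("coefficients must be a named numeric vector")
    }
    unknown <- setdiff(names(coefficients), names(default_coef))
    if (length(unknown)) {
      stop("unknown coefficient(s) for strategy '", pan_model, "': ",
           paste(unknown, collapse = ", "))
    }
    default_coef[names(coefficients)] <- coefficients
  }
  structure(
    list(pan_model = pan_model, et_pan_fraction = et_pan_fraction,
         coefficients = default_coef),
    class = "et_params"
  )
}

#' Daily open-pan evaporation from radiation and temperature
#'
#' Estimates open-pan evaporation from potential (extraterrestrial) solar
#' radiation, mean air temperature, and the daily temperature range as a
#' cloud-cover proxy, using the strategy configured in \code{params}
#' (see \code{\link{et_params}}).
#'
#' @param ra Extraterrestrial radiation, MJ m-2 day-1 (>= 0). Vectorised.
#' @param t_mean Daily mean air temperature, degrees C.
#' @param t_range Daily temperature range \code{t_max - t_min}, degrees C
#'   (>= 0).
#' @param params An \code{\link{et_params}} object.
#' @return Pan evaporation, mm/day (>= 0).
#' @examples
#' pan_evaporation(40, 20, 10, et_params())
#' @export
pan_evaporation <- function(ra, t_mean, t_range, params = et_params()) {
  stopifnot(inherits(params, "et_params"))
  if (any(ra < 0)) stop("ra must be >= 0")
  if (any(t_range < 0)) stop("t_range must be >= 0")
  co <- params$coefficients
  pan <- switch(params$pan_model,
    hargreaves = co[["k"]] * (ra / 2.45) * (t_mean + 17.8) * sqrt(t_range),
    linear = co[["b0"]] + co[["b1"]] * ra + co[["b2"]] * t_mean +
      co[["b3"]] * t_range
  )
  pmax(0, pan)
}

#' Plant evapotranspiration as a fraction of pan evaporation
#'
#' @param pan Pan evaporation, mm/day (>= 0). Vectorised.
#' @param params An \code{\link{et_params}} object; uses
#'   \code{et_pan_fraction}.
#' @return Evapotranspiration, mm/day.
#' @examples
#' evapotranspiration(5, et_params(et_pan_fraction = 0.8))  # 4.0
#' @export
evapotranspiration <- function(pan, params = et_params()) {
  stopifnot(inherits(params, "et_params"))
  if (any(pan < 0)) stop("pan must be >= 0")
  params$et_pan_fraction * pan
}

#' Soil water bucket state
#'
#' @param asw Current plant-available soil water, mm, in \code{[0, asw_max]}.
#' @param asw_max Maximum plant-available soil water the soil can hold, mm
#'   (> 0). Soil-survey values given in inches convert at 25.4 mm/inch.
#' @return An object of class \code{soil_water}.
#' @export
soil_water <- function(asw, asw_max) {
  if (!is.numeric(asw_max) || length(asw_max) != 1L || asw_max <= 0) {
    stop("asw_max must be a single positive number (mm)")
  }
  if (!is.numeric(asw) || length(asw) != 1L || asw < 0 || asw > asw_max) {
    stop("asw must lie in [0, asw_max]")
  }
  structure(list(asw = asw, asw_max = asw_max), class = "soil_water")
}

#' Advance the soil water bucket one day
#'
#' The new store is the previous day's water plus precipitation minus
#' evapotranspiration, capped at \code{asw_max} and floored at 0. Clamping is
#' the contract, not an error: excess water is treated as runoff/drainage and
#' the store cannot go negative.
#'
#' @param state A \code{\link{soil_water}} state.
#' @param precip Precipitation, mm (>= 0).
#' @param et Evapotranspiration, mm (>= 0).
#' @return Updated \code{soil_water} state; \code{asw_max} is unchanged.
#' @examples
#' update_asw(soil_water(127, 127), precip = 30, et = 4)  # stays capped
#' @export
update_asw <- function(state, precip, et) {
  stopifnot(inherits(state, "soil_water"))
  if (precip < 0) stop("precip must be >= 0")
  if (et < 0) stop("et must be >= 0")
  state$asw <- min(state$asw_max, max(0, state$asw + precip - et))
  state
}

# shared ramp: 1 above half-full, linear 2*(asw/asw_max) below
.asw_ramp <- function(asw, asw_max) {
  frac <- asw / asw_max
  ifelse(frac >= 0.5, 1, pmax(0, 2 * frac))
}

#' Relative growth rate factor for plant-available soil water
#'
#' 1.0 while the store is above half of \code{asw_max}, declining linearly to
#' 0.0 as the store empties.
#'
#' @param state A \code{\link{soil_water}} state, or a numeric \code{asw}
#'   when \code{asw_max} is given.
#' @param asw_max Optional numeric \code{asw_max} for the vectorised numeric
#'   form.
#' @return Dimensionless factor in \code{[0, 1]}.
#' @examples
#' rgr_asw(soil_water(0.25 * 127, 127))  # 0.5
#' @export
rgr_asw <- function(state, asw_max = NULL) {
  if (inherits(state, "soil_water")) {
    .asw_ramp(state$asw, state$asw_max)
  } else {
    if (is.null(asw_max)) stop("asw_max required when state is numeric")
    .asw_ramp(state, asw_max)
  }
}

#' Relative growth rate factor for soil biology
#'
#' Soil biological activity (mineralisation supplying nitrogen and other
#' nutrients) responds to soil water with the same ramp as plant growth:
#' 1.0 above half of \code{asw_max}, linear to 0.0 at an empty store. Kept as
#' a separate function so the two factors can be parameterised independently
#' in future.
#'
#' @inheritParams rgr_asw
#' @return Dimensionless factor in \code{[0, 1]}.
#' @export
rgr_sbio <- function(state, asw_max = NULL) {
  rgr_asw(state, asw_max)
}
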