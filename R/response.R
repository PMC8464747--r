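# Plant growth response functions: cardinal-temperature trapezoid and the
# daylength ramps, with named parameter presets for cool-season (C3) and
# warm-season (C4) forages.

#' Plant response parameters
#'
#' Cardinal temperatures of the trapezoidal temperature response, daylength
#' thresholds of the photoperiod response, and the thermal-time threshold
#' that initiates spring growth.
#'
#' @param low_min_pgt Temperature (degrees C) at which growth starts, the
#'   lower zero of the trapezoid.
#' @param low_op_pgt Lower optimum temperature: growth reaches 1.0 here.
#' @param high_op_pgt Upper optimum temperature: growth stays at 1.0 up to
#'   here.
#' @param high_max_pgt Temperature at which growth falls back to 0.0.
#' @param dl_floor Daylength (h) below which growth is 0 in both phases.
#' @param dl_spring_opt Daylength (h) at which the spring (ascending) ramp
#'   reaches 1.0.
#' @param dl_fall_opt Daylength (h) down to which the late-summer
#'   (descending) response stays at 1.0 before ramping back to
#'   \code{dl_floor}.
#' @param tsum_start Accumulated thermal time (degree C days of positive
#'   daily means from 1 January) at which spring growth initiates.
#' @param et_pan_fraction Optional plant-type override of the
#'   evapotranspiration / pan-evaporation fraction (\code{NULL} keeps the
#'   site's value).
#' @return An object of class \code{plant_params}.
#' @seealso \code{\link{c3_defaults}}, \code{\link{c4_defaults}}
#' @export
plant_params <- function(low_min_pgt, low_op_pgt, high_op_pgt, high_max_pgt,
                         dl_floor = 8, dl_spring_opt = 12, dl_fall_opt = 13,
                         tsum_start = 280, et_pan_fraction = NULL) {
  if (!(low_min_pgt < low_op_pgt && low_op_pgt <= high_op_pgt &&
        high_op_pgt < high_max_pgt)) {
    stop("cardinal temperatures must satisfy ",
         "low_min_pgt < low_op_pgt <= high_op_pgt < high_max_pgt")
  }
  if (!(dl_floor < dl_spring_opt && dl_spring_opt <= dl_fall_opt)) {
    stop("daylength thresholds must satisfy dl_floor < dl_spring_opt <= dl_fall_opt")
  }
  if (tsum_start <= 0) stop("tsum_start must be > 0")
  if (!is.null(et_pan_fraction) &&
      (et_pan_fraction <= 0 || et_pan_fraction > 1)) {
    stop("et_pan_fraction override must be in (0, 1]")
  }
  structure(
    list(low_min_pgt = low_min_pgt, low_op_pgt = low_op_pgt,
         high_op_pgt = high_op_pgt, high_max_pgt = high_max_pgt,
         dl_floor = dl_floor, dl_spring_opt = dl_spring_opt,
         dl_fall_opt = dl_fall_opt, tsum_start = tsum_start,
         et_pan_fraction = et_pan_fraction),
    class = "plant_params"
  )
}

#' Cool-season (C3) grass defaults
#'
#' Cardinal temperatures 0/10/20/30 degrees C, daylength thresholds
#' 8/12/13 h, thermal-time initiation threshold 280 degree C days
#' (overridable; 300 suits some sites).
#'
#' @param tsum_start Thermal-time initiation threshold, degree C days.
#' @return A \code{\link{plant_params}} object.
#' @examples
#' c3_defaults()
#' c3_defaults(tsum_start = 300)
#' @export
c3_defaults <- function(tsum_start = 280) {
  plant_params(0, 10, 20, 30, dl_floor = 8, dl_spring_opt = 12,
               dl_fall_opt = 13, tsum_start = tsum_start)
}

#' Warm-season (C4) grass defaults
#'
#' Shifts the lower cardinal points upward (minimum 10 degrees C, lower
#' optimum 30 degrees C) and lowers the evapotranspiration / pan-evaporation
#' fraction to 0.75. The upper cardinal points and the daylength thresholds
#' have no established warm-season values here; they default to plausible
#' placeholders (upper optimum 35, maximum 45 degrees C, C3 daylength
#' thresholds) and should be reviewed before serious C4 use.
#'
#' @param high_op_pgt Upper optimum temperature placeholder, degrees C.
#' @param high_max_pgt Upper maximum temperature placeholder, degrees C.
#' @param tsum_start Thermal-time initiation threshold, degree C days.
#' @return A \code{\link{plant_params}} object with
#'   \code{et_pan_fraction = 0.75}.
#' @export
c4_defaults <- function(high_op_pgt = 35, high_max_pgt = 45,
                        tsum_start = 280) {
  plant_params(10, 30, high_op_pgt, high_max_pgt, dl_floor = 8,
               dl_spring_opt = 12, dl_fall_opt = 13,
               tsum_start = tsum_start, et_pan_fraction = 0.75)
}

#' Temperature relative growth rate factor
#'
#' Piecewise-linear trapezoid over the four cardinal temperatures: 0 at or
#' below \code{low_min_pgt}, rising linearly to 1 at \code{low_op_pgt},
#' flat at 1 through \code{high_op_pgt}, falling linearly to 0 at
#' \code{high_max_pgt}, and 0 beyond.
#'
#' @param t_mean Daily mean air temperature, degrees C
#'   (\code{(t_min + t_max)/2}). Vectorised.
#' @param p A \code{\link{plant_params}} object.
#' @return Dimensionless factor in \code{[0, 1]}.
#' @examples
#' rgr_temp(c(-5, 5, 15, 25, 35), c3_defaults())
#' @export
rgr_temp <- function(t_mean, p = c3_defaults()) {
  stopifnot(inherits(p, "plant_params"))
  up <- (t_mean - p$low_min_pgt) / (p$low_op_pgt - p$low_min_pgt)
  down <- (p$high_max_pgt - t_mean) / (p$high_max_pgt - p$high_op_pgt)
  pmax(0, pmin(1, up, down))
}

#' Daylength relative growth rate factor
#'
#' In the ascending (spring) half of the year the response is 0 below
#' \code{dl_floor}, rises linearly to 1 at \code{dl_spring_opt}, and stays at
#' 1 for longer days. In the descending (late-summer) half it stays at 1
#' until daylength falls to \code{dl_fall_opt}, then declines linearly to 0
#' at \code{dl_floor}.
#'
#' @param daylength Daylength, hours, in \code{[0, 24]}. Vectorised.
#' @param phase \code{"ascending"} (before the summer solstice) or
#'   \code{"descending"} (after). May be a vector matching
#'   \code{daylength}.
#' @param p A \code{\link{plant_params}} object.
#' @return Dimensionless factor in \code{[0, 1]}.
#' @examples
#' rgr_daylength(12, "ascending")   # 1
#' rgr_daylength(10.5, "descending")  # 0.5
#' @export
rgr_daylength <- function(daylength, phase, p = c3_defaults()) {
  stopifnot(inherits(p, "plant_params"))
  if (any(daylength < 0 | daylength > 24)) {
    stop("daylength must lie in [0, 24] hours")
  }
  phase <- match.arg(phase, c("ascending", "descending"), several.ok = TRUE)
  phase <- rep_len(phase, length(daylength))
  asc <- (daylength - p$dl_floor) / (p$dl_spring_opt - p$dl_floor)
  desc <- (daylength - p$dl_floor) / (p$dl_fall_opt - p$dl_floor)
  pmax(0, pmin(1, ifelse(phase == "ascending", asc, desc)))
}
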