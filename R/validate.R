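# Model testing machinery: relative observed growth, pairing observations
# with simulated cum_rgr_env, the observed ~ modelled regression with its
# criteria (R-squared, SDreg, AAPE), and drought impact ratios.

#' Express observed cumulative growth as a percent of the site maximum
#'
#' Relative observed forage growth (relFGobs) is cumulative observed growth
#' divided by the highest cumulative growth observed across all years at the
#' site, times 100. In \code{"auto"} mode the reference is the maximum
#' \code{cum_fg_obs} in the data, so the best event maps to exactly 100.
#'
#' @param events Observation data frame with a \code{cum_fg_obs} column
#'   (kg DM/ha), e.g. from \code{\link{read_observations}}.
#' @param reference_max Reference maximum in kg DM/ha, or \code{"auto"}.
#' @return \code{events} with an added \code{rel_fg_obs} column (percent).
#' @export
relative_growth <- function(events, reference_max = "auto") {
  if (nrow(events) == 0L) stop("no observation events")
  if (identical(reference_max, "auto")) {
    reference_max <- max(events$cum_fg_obs)
  }
  if (!is.numeric(reference_max) || reference_max <= 0) {
    stop("reference_max must be a positive number or \"auto\"")
  }
  events$rel_fg_obs <- 100 * events$cum_fg_obs / reference_max
  events
}

#' Pair observation events with simulated daily state
#'
#' Looks up \code{cum_rgr_env} on each event's (year, doy). Every event must
#' have a simulated day; unmatched events are an error, never silently
#' dropped.
#'
#' @param events Observation data frame (columns \code{year}, \code{doy},
#'   \code{cum_fg_obs}, optionally \code{rel_fg_obs}, \code{treatment},
#'   \code{replicate}).
#' @param states Daily-state data frame from \code{\link{simulate_growth}}.
#' @return \code{events} with an added \code{cum_rgr_env} column.
#' @export
pair_with_model <- function(events, states) {
  if (nrow(events) == 0L) stop("no observation events")
  key_e <- paste(events$year, events$doy)
  key_s <- paste(states$year, states$doy)
  idx <- match(key_e, key_s)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("observation event(s) with no simulated day: ",
         paste0("(year ", events$year[bad], ", doy ", events$doy[bad], ")",
                collapse = ", "))
  }
  events$cum_rgr_env <- states$cum_rgr_env[idx]
  events
}

#' Regress observed growth on modelled cumulative growth rate
#'
#' Ordinary least squares of an observed response (\code{cum_fg_obs} or
#' \code{rel_fg_obs}) on the model's \code{cum_rgr_env}, optionally with
#' year and/or treatment dummy variables in treatment (reference-level)
#' coding, the earliest year / first treatment being the reference. Reports
#' the three test criteria:
#' \itemize{
#'   \item \code{r2}: coefficient of determination of the full model;
#'   \item \code{sd_reg}: standard deviation of residuals about the
#'     regression, \eqn{\sqrt{SSE/(n-k)}} with \eqn{k} estimated
#'     coefficients (the square root of the regression mean square error);
#'   \item \code{aape}: average absolute percent error,
#'     \eqn{(100/n)\sum |obs - fitted|/obs}.
#' }
#' The intercept is additionally tested against zero at p = 0.05
#' (\code{intercept_zero_flag} is \code{TRUE} when it does NOT differ from
#' zero).
#'
#' @param pairs Data frame from \code{\link{pair_with_model}}.
#' @param response Response column, \code{"rel_fg_obs"} or
#'   \code{"cum_fg_obs"}.
#' @param dummies Which dummy effects to include: \code{"none"},
#'   \code{"year"} or \code{"year+treatment"}.
#' @return An object of class \code{fit_result}: list with
#'   \code{intercept}, \code{intercept_se}, \code{slope}, \code{slope_se},
#'   \code{dummy_effects} (named numeric), \code{r2}, \code{sd_reg},
#'   \code{aape}, \code{n}, \code{intercept_zero_flag}, \code{model}
#'   (the underlying \code{lm}).
#' @examples
#' d <- data.frame(cum_rgr_env = 1:10, rel_fg_obs = 5 + 2 * (1:10))
#' fit_observed_vs_modelled(d)   # exact: slope 2, intercept 5, r2 = 1
#' @export
fit_observed_vs_modelled <- function(pairs,
                                     response = "rel_fg_obs",
                                     dummies = c("none", "year",
                                                 "year+treatment")) {
  dummies <- match.arg(dummies)
  if (!response %in% names(pairs)) {
    stop("response column '", response, "' not present; run relative_growth() ",
         "first for rel_fg_obs")
  }
  if (!"cum_rgr_env" %in% names(pairs)) {
    stop("pairs lack cum_rgr_env; run pair_with_model() first")
  }
  d <- data.frame(y = pairs[[response]], cum_rgr_env = pairs$cum_rgr_env)
  terms <- "cum_rgr_env"
  if (dummies %in% c("year", "year+treatment")) {
    d$year <- factor(pairs$year, levels = sort(unique(pairs$year)))
    if (nlevels(d$year) < 2L) stop("year dummies requested but only one year present")
    terms <- c(terms, "year")
  }
  if (dummies == "year+treatment") {
    d$treatment <- factor(pairs$treatment)
    if (nlevels(d$treatment) < 2L) {
      stop("treatment dummies requested but only one treatment present")
    }
    terms <- c(terms, "treatment")
  }
  k <- 2L + sum(vapply(d[setdiff(terms, "cum_rgr_env")], nlevels, 1L) - 1L)
  if (nrow(d) < k + 2L) {
    stop("too few observations (", nrow(d), ") for ", k, " coefficients")
  }
  fml <- stats::reformulate(terms, response = "y")
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    stop("collinear design: some dummy coefficients are not estimable")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  n <- nrow(d)
  res <- stats::residuals(fit)
  sd_reg <- sqrt(sum(res^2) / stats::df.residual(fit))
  obs <- d$y
  if (any(obs == 0)) {
    stop("AAPE undefined: observed value of 0 present; exclude such events")
  }
  aape <- 100 / n * sum(abs(res) / abs(obs))
  dummy_rows <- setdiff(rownames(co), c("(Intercept)", "cum_rgr_env"))
  structure(
    list(intercept = co["(Intercept)", "Estimate"],
         intercept_se = co["(Intercept)", "Std. Error"],
         slope = co["cum_rgr_env", "Estimate"],
         slope_se = co["cum_rgr_env", "Std. Error"],
         dummy_effects = stats::setNames(co[dummy_rows, "Estimate"],
                                         dummy_rows),
         r2 = sm$r.squared,
         sd_reg = sd_reg,
         aape = aape,
         n = n,
         intercept_zero_flag = co["(Intercept)", "Pr(>|t|)"] >= 0.05,
         model = fit),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d\n", x$n))
  cat(sprintf("  intercept %8.3f (se %.3f)%s\n", x$intercept, x$intercept_se,
              if (x$intercept_zero_flag) "  [not different from 0 at p = 0.05]" else ""))
  cat(sprintf("  slope     %8.4f (se %.4f)\n", x$slope, x$slope_se))
  if (length(x$dummy_effects)) {
    cat("  dummy effects:\n")
    for (nm in names(x$dummy_effects)) {
      cat(sprintf("    %-14s %8.3f\n", nm, x$dummy_effects[[nm]]))
    }
  }
  cat(sprintf("  R2 = %.3f   SDreg = %.3f   AAPE = %.2f%%\n",
              x$r2, x$sd_reg, x$aape))
  invisible(x)
}

#' Serialise a fit result to JSON
#'
#' @param x A \code{fit_result}.
#' @param path Optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to \code{path}.
#' @export
fit_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "fit_result"))
  obj <- x[c("intercept", "intercept_se", "slope", "slope_se",
             "dummy_effects", "r2", "sd_reg", "aape", "n",
             "intercept_zero_flag")]
  obj$dummy_effects <- as.list(obj$dummy_effects)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Ratio of two end-of-year totals (drought impact)
#'
#' The impact of a drought year is expressed as the ratio of its end-of-year
#' total (observed cumulative forage growth, or modelled cumulative
#' environmental growth rate) to a reference year's total.
#'
#' @param total_a Drought-year total (numerator).
#' @param total_b Reference-year total (denominator, non-zero).
#' @param digits Decimal places to round to; \code{NULL} for no rounding.
#' @return The ratio \code{total_a / total_b}.
#' @examples
#' drought_impact_ratio(3323, 5736)  # 0.58
#' @export
drought_impact_ratio <- function(total_a, total_b, digits = 2) {
  if (total_b == 0) stop("reference-year total is zero; ratio undefined")
  r <- total_a / total_b
  if (!is.null(digits)) r <- round(r, digits)
  r
}
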