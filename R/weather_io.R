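# Reading, validating and writing daily weather series, observation tables
# and daily model state.
#
# Weather CSV schema (dialect "year_doy", the default):
#   year,doy,tmax_c,tmin_c,precip_mm
# Dialect "date" replaces year,doy with an ISO-8601 `date` column.
# Lines starting with '#' are skipped. Gap policy on ingestion: missing
# calendar days inside the span are inserted; temperature gaps of up to 3
# consecutive days are filled by linear interpolation (longer gaps are an
# error); missing precipitation becomes 0 with a warning -- interpolation
# never invents rainfall.

.date_to_year_doy <- function(date) {
  d <- as.Date(date, format = "%Y-%m-%d")
  list(year = as.integer(format(d, "%Y")), doy = as.integer(format(d, "%j")),
       bad = is.na(d))
}

.year_doy_to_date <- function(year, doy) {
  as.Date(doy - 1, origin = as.Date(paste0(year, "-01-01")))
}

.days_in_year <- function(year) ifelse(is_leap_year(year), 366L, 365L)

# fill NA runs of length <= max_run by linear interpolation between the
# flanking values; longer runs or boundary runs are an error
.interpolate_gaps <- function(x, max_run, what) {
  if (!anyNA(x)) return(list(x = x, n_filled = 0L))
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    if (r$lengths[i] > max_run) {
      stop(what, ": gap of ", r$lengths[i], " consecutive days (rows ",
           starts[i], "-", ends[i], ") exceeds the ", max_run,
           "-day interpolation limit")
    }
    if (starts[i] == 1L || ends[i] == length(x)) {
      stop(what, ": gap at the start or end of the series cannot be interpolated")
    }
  }
  n_filled <- sum(is.na(x))
  idx <- which(!is.na(x))
  x <- stats::approx(idx, x[idx], xout = seq_along(x))$y
  list(x = x, n_filled = n_filled)
}

#' Weather series constructor
#'
#' Validates and wraps an ordered daily weather table. Normally produced by
#' \code{\link{read_weather}} or \code{\link{generate_weather}}.
#'
#' @param records Data frame with columns \code{year}, \code{doy},
#'   \code{t_min}, \code{t_max}, \code{precip} (degrees C and mm/day).
#' @param site Site label.
#' @return An object of class \code{weather_series}.
#' @export
weather_series <- function(records, site = "site") {
  need <- c("year", "doy", "t_min", "t_max", "precip")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("weather records missing column(s): ", paste(miss, collapse = ", "))
  }
  records <- records[need]
  records$year <- as.integer(records$year)
  records$doy <- as.integer(records$doy)
  if (nrow(records) == 0L) {
    return(structure(list(site = site, records = records),
                     class = "weather_series"))
  }
  if (any(records$doy < 1L | records$doy > .days_in_year(records$year))) {
    bad <- which(records$doy < 1L | records$doy > .days_in_year(records$year))[1]
    stop("row ", bad, ": doy ", records$doy[bad],
         " invalid for year ", records$year[bad])
  }
  o <- order(records$year, records$doy)
  records <- records[o, , drop = FALSE]
  key <- records$year * 1000L + records$doy
  if (anyDuplicated(key)) {
    stop("duplicate day: year ", records$year[which(duplicated(key))[1]],
         " doy ", records$doy[which(duplicated(key))[1]])
  }
  if (any(diff(.year_doy_to_date(records$year, records$doy)) != 1)) {
    stop("weather series has calendar gaps after ingestion")
  }
  bad <- which(records$t_max < records$t_min)
  if (length(bad)) {
    stop("row ", bad[1], " (year ", records$year[bad[1]], " doy ",
         records$doy[bad[1]], "): t_max (", records$t_max[bad[1]],
         ") < t_min (", records$t_min[bad[1]], ")")
  }
  if (any(records$precip < 0)) {
    bad <- which(records$precip < 0)[1]
    stop("row ", bad, ": negative precipitation ", records$precip[bad])
  }
  rownames(records) <- NULL
  structure(list(site = site, records = records), class = "weather_series")
}

#' @export
print.weather_series <- function(x, ...) {
  r <- x$records
  cat("<weather_series> site '", x$site, "': ", nrow(r), " days, ",
      min(r$year), "-", max(r$year), "\n", sep = "")
  invisible(x)
}

#' Read a daily weather CSV
#'
#' Reads, validates and gap-fills a daily weather series. See the schema and
#' gap policy in the package README: columns
#' \code{year,doy,tmax_c,tmin_c,precip_mm} (dialect \code{"year_doy"}) or
#' \code{date,tmax_c,tmin_c,precip_mm} with ISO dates (dialect
#' \code{"date"}). Missing calendar days within the span are inserted and
#' treated as gaps. Temperature gaps of at most 3 consecutive days are
#' linearly interpolated (with a warning); missing precipitation becomes 0
#' (with a warning).
#'
#' @param path Path to the CSV file.
#' @param dialect Schema dialect, \code{"year_doy"} or \code{"date"}.
#' @param site Site label attached to the series (default: file name).
#' @return A \code{\link{weather_series}}.
#' @export
read_weather <- function(path, dialect = c("year_doy", "date"),
                         site = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("weather file not found: ", path)
  raw <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- if (dialect == "year_doy") {
    c("year", "doy", "tmax_c", "tmin_c", "precip_mm")
  } else {
    c("date", "tmax_c", "tmin_c", "precip_mm")
  }
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("weather file ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (dialect == "date") {
    yd <- .date_to_year_doy(raw$date)
    if (any(yd$bad)) {
      stop("line ", which(yd$bad)[1] + 1L, ": unparseable date '",
           raw$date[which(yd$bad)[1]], "' (expected YYYY-MM-DD)")
    }
    raw$year <- yd$year
    raw$doy <- yd$doy
  }
  df <- data.frame(year = as.integer(raw$year), doy = as.integer(raw$doy),
                   t_min = as.numeric(raw$tmin_c),
                   t_max = as.numeric(raw$tmax_c),
                   precip = as.numeric(raw$precip_mm))
  bad <- which(!is.na(df$t_min) & !is.na(df$t_max) & df$t_max < df$t_min)
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ": t_max (", df$t_max[bad[1]],
         ") < t_min (", df$t_min[bad[1]], ")")
  }
  # insert missing calendar days across the span, then apply the gap policy
  dates <- .year_doy_to_date(df$year, df$doy)
  if (anyNA(dates)) stop("invalid year/doy combination in ", path)
  full <- seq(min(dates), max(dates), by = "day")
  idx <- match(full, dates)
  if (anyNA(idx)) {
    df <- df[idx, , drop = FALSE]
    df$year <- as.integer(format(full, "%Y"))
    df$doy <- as.integer(format(full, "%j"))
  }
  for (col in c("t_min", "t_max")) {
    filled <- .interpolate_gaps(df[[col]], max_run = 3L, what = col)
    if (filled$n_filled > 0L) {
      warning("filled ", filled$n_filled, " missing ", col,
              " value(s) by linear interpolation", call. = FALSE)
    }
    df[[col]] <- filled$x
  }
  if (anyNA(df$precip)) {
    warning("set ", sum(is.na(df$precip)),
            " missing precipitation value(s) to 0 (never interpolated)",
            call. = FALSE)
    df$precip[is.na(df$precip)] <- 0
  }
  weather_series(df, site = site)
}

#' Write a weather series to CSV
#'
#' Writes in the default \code{year_doy} dialect so the file round-trips
#' through \code{\link{read_weather}}.
#'
#' @param series A \code{\link{weather_series}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_weather <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  r <- series$records
  out <- data.frame(year = r$year, doy = r$doy, tmax_c = r$t_max,
                    tmin_c = r$t_min, precip_mm = r$precip)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observed forage growth table
#'
#' Expects columns \code{year,doy,cum_fg_obs_kg_ha,treatment,replicate}:
#' cumulative forage growth (kg dry matter/ha) for the year up to the event
#' day, with treatment and replicate labels. Rows are ordered by
#' (treatment, replicate, year, doy). A decrease of cumulative growth within
#' a year and paddock is logged as a warning but rows are kept.
#'
#' @param path Path to the CSV file.
#' @return Data frame of class \code{observation_events} with columns
#'   \code{year}, \code{doy}, \code{cum_fg_obs}, \code{treatment},
#'   \code{replicate}.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("year", "doy", "cum_fg_obs_kg_ha", "treatment", "replicate")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("observations file ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  ev <- data.frame(year = as.integer(raw$year), doy = as.integer(raw$doy),
                   cum_fg_obs = as.numeric(raw$cum_fg_obs_kg_ha),
                   treatment = as.character(raw$treatment),
                   replicate = as.character(raw$replicate))
  if (any(is.na(ev$cum_fg_obs) | ev$cum_fg_obs < 0)) {
    bad <- which(is.na(ev$cum_fg_obs) | ev$cum_fg_obs < 0)[1]
    stop("line ", bad + 1L, ": cum_fg_obs_kg_ha must be a non-negative number")
  }
  ev <- ev[order(ev$treatment, ev$replicate, ev$year, ev$doy), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) > 1L) {
    grp <- interaction(ev$treatment, ev$replicate, ev$year, drop = TRUE)
    dec <- unlist(tapply(ev$cum_fg_obs, grp, function(x) c(FALSE, diff(x) < 0)),
                  use.names = FALSE)
    if (any(dec)) {
      warning(sum(dec), " observation(s) with decreasing cumulative growth ",
              "within a year/paddock; rows kept", call. = FALSE)
    }
  }
  class(ev) <- c("observation_events", "data.frame")
  ev
}

#' Write simulated daily state to CSV
#'
#' One row per simulated day with all model quantities, in a fixed column
#' order. Values round-trip through \code{read.csv} to at least 6 decimals.
#'
#' @param states Data frame of daily states from \code{\link{simulate_growth}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_daily_states <- function(states, path) {
  if (!is.data.frame(states) || nrow(states) == 0L) {
    stop("refusing to write an empty daily-state series")
  }
  miss <- setdiff(DAILY_STATE_COLUMNS, names(states))
  if (length(miss)) {
    stop("daily-state table missing column(s): ", paste(miss, collapse = ", "))
  }
  utils::write.csv(states[DAILY_STATE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read simulated daily state back from CSV
#'
#' @param path Path written by \code{\link{write_daily_states}}.
#' @return Data frame with the daily-state columns.
#' @export
read_daily_states <- function(path) {
  if (!file.exists(path)) stop("daily-state file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(DAILY_STATE_COLUMNS, names(df))
  if (length(miss)) {
    stop("daily-state file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df$growth_active <- as.logical(df$growth_active)
  df
}
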