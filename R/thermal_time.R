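# Thermal time: daily and cumulative growing degree-days from daily
# temperature records, by the daily-mean method or the single-sine method.

#' Construct a daily climate series
#'
#' A climate series holds one row per calendar day with minimum, maximum and
#' mean air temperature. It is the sole environmental driver of the growth
#' simulator: thermal time is accumulated from it.
#'
#' @param dates `Date` vector, strictly increasing, no gaps.
#' @param tmin,tmax,tmean daily temperatures in degrees Celsius. `tmean`
#'   defaults to `(tmin + tmax) / 2`.
#' @return An object of class `climate_series`: a data frame with columns
#'   `date`, `tmin`, `tmax`, `tmean`.
#' @export
climate_series <- function(dates, tmin, tmax, tmean = (tmin + tmax) / 2) {
  dates <- as.Date(dates)
  n <- length(dates)
  stopifnot(length(tmin) == n, length(tmax) == n, length(tmean) == n)
  if (n > 1) {
    dd <- as.integer(diff(dates))
    if (any(dd <= 0)) stop("dates must be strictly increasing")
    if (any(dd != 1)) stop("climate series has gaps: dates must be consecutive days")
  }
  if (any(tmin > tmax)) stop("tmin > tmax on ", sum(tmin > tmax), " day(s)")
  bad <- tmean < tmin | tmean > tmax
  if (any(bad)) stop("tmean outside [tmin, tmax] on ", sum(bad), " day(s)")
  out <- data.frame(date = dates, tmin = tmin, tmax = tmax, tmean = tmean)
  class(out) <- c("climate_series", "data.frame")
  out
}

#' Read a climate series from CSV
#'
#' Expects a header with columns `date` (ISO-8601), `tmin`, `tmax` and
#' optionally `tmean`.
#'
#' @param path path to the CSV file.
#' @return A [climate_series()] object.
#' @export
read_climate_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("climate CSV missing column(s): ", paste(miss, collapse = ", "))
  if ("tmean" %in% names(x)) {
    climate_series(as.Date(x$date), x$tmin, x$tmax, x$tmean)
  } else {
    climate_series(as.Date(x$date), x$tmin, x$tmax)
  }
}

#' Write a climate series to CSV
#'
#' @param climate a [climate_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(climate, path) {
  utils::write.csv(as.data.frame(climate), path, row.names = FALSE)
  invisible(path)
}

#' Thermal-time accumulation parameters
#'
#' Base and upper temperature thresholds between which degree-days
#' accumulate, and the accumulation method. Defaults are 7 and 35 degrees C,
#' the thresholds used for temperate fruit trees.
#'
#' @param t_base lower threshold (degrees C); no accumulation below it.
#' @param t_upper upper threshold (degrees C); accumulation is capped there
#'   (horizontal cutoff: heat above `t_upper` counts as `t_upper`).
#' @param method `"single_sine"` (default) or `"mean"`.
#' @return An object of class `thermal_time_params`.
#' @export
thermal_time_params <- function(t_base = 7, t_upper = 35,
                                method = c("single_sine", "mean")) {
  method <- match.arg(method)
  stopifnot(is.numeric(t_base), is.numeric(t_upper))
  if (!(t_base < t_upper)) stop("t_base must be strictly below t_upper")
  structure(list(t_base = t_base, t_upper = t_upper, method = method),
            class = "thermal_time_params")
}

#' Daily degree-days from the mean temperature
#'
#' `max(0, min(tmean, t_upper) - t_base)`: the day's mean temperature,
#' clamped to the upper threshold, minus the base. The upper cap is applied
#' here too, for symmetry with the single-sine method.
#'
#' @param tmean daily mean temperature(s), degrees C. Vectorised.
#' @param params a [thermal_time_params()].
#' @return Degree-days (GDD), same length as `tmean`.
#' @export
daily_gdd_mean <- function(tmean, params = thermal_time_params(method = "mean")) {
  pmax(0, pmin(tmean, params$t_upper) - params$t_base)
}

#' Daily degree-days by the single-sine method
#'
#' Models the within-day temperature course as one symmetric sine cycle
#' between `tmin` and `tmax` and integrates the part of the curve lying
#' between the base and upper thresholds; temperature above the upper
#' threshold contributes at the `t_upper` rate (horizontal cutoff).
#'
#' Closed-form cases: when the whole curve lies between the thresholds the
#' result is `tmean - t_base`; entirely below base gives 0; entirely above
#' the upper threshold gives `t_upper - t_base`.
#'
#' @param tmin,tmax daily temperature extremes, degrees C. Vectorised;
#'   `tmin <= tmax` is required.
#' @param params a [thermal_time_params()].
#' @return Degree-days (GDD).
#' @export
daily_gdd_single_sine <- function(tmin, tmax, params = thermal_time_params()) {
  if (any(tmin > tmax)) stop("tmin > tmax")
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  lo <- params$t_base; up <- params$t_upper
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  dd <- numeric(n)
  for (i in seq_len(n)) {
    dd[i] <- .single_sine_one(m[i], a[i], lo, up)
  }
  dd
}

# One day: integrate max(0, min(T(t), up) - lo) over T(t) = m + a*sin(2*pi*t).
# Degree-days in each threshold case follow from integrating the sine
# between its crossing angles (Baskerville-Emin construction).
.single_sine_one <- function(m, a, lo, up) {
  tmin <- m - a; tmax <- m + a
  if (tmax <= lo) return(0)
  if (tmin >= up) return(up - lo)
  if (tmin >= lo && tmax <= up) return(m - lo)
  if (a == 0) return(min(m, up) - lo)  # remaining cases need a crossing
  if (tmin < lo && tmax <= up) {
    # intercepted by the base threshold only
    th <- asin((lo - m) / a)
    return(((m - lo) * (pi / 2 - th) + a * cos(th)) / pi)
  }
  if (tmin >= lo && tmax > up) {
    # intercepted by the upper threshold only
    ph <- asin((up - m) / a)
    return(((m - lo) * (ph + pi / 2) + (up - lo) * (pi / 2 - ph) - a * cos(ph)) / pi)
  }
  # intercepted by both thresholds
  th <- asin((lo - m) / a)
  ph <- asin((up - m) / a)
  ((m - lo) * (ph - th) + a * (cos(th) - cos(ph)) + (up - lo) * (pi / 2 - ph)) / pi
}

#' Seasonal thermal-time series
#'
#' Computes per-day and cumulative degree-days over a window of a climate
#' series, inclusive of both endpoints. Day 1 of the returned series is the
#' start date (budburst); the default growing season used throughout the
#' package is April 15 to September 30.
#'
#' @param climate a [climate_series()].
#' @param params a [thermal_time_params()].
#' @param start,end window bounds (`Date` or coercible); both inclusive.
#' @return An object of class `thermal_time_series`: list with `dates`,
#'   `tt_d` (daily GDD) and `cumulative` (running sum).
#' @export
season_thermal_time <- function(climate, params = thermal_time_params(),
                                start = NULL, end = NULL) {
  if (is.null(start)) start <- climate$date[1]
  if (is.null(end)) end <- climate$date[nrow(climate)]
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("empty window: start is after end")
  keep <- climate$date >= start & climate$date <= end
  x <- climate[keep, , drop = FALSE]
  n_expected <- as.integer(end - start) + 1L
  if (nrow(x) != n_expected) {
    stop("climate series does not cover the window: ",
         n_expected - nrow(x), " day(s) missing")
  }
  tt_d <- switch(params$method,
    mean = daily_gdd_mean(x$tmean, params),
    single_sine = daily_gdd_single_sine(x$tmin, x$tmax, params)
  )
  structure(list(dates = x$date, tt_d = tt_d, cumulative = cumsum(tt_d)),
            class = "thermal_time_series")
}

#' @export
print.thermal_time_series <- function(x, ...) {
  cat("<thermal_time_series> ", length(x$tt_d), " days, ",
      format(x$dates[1]), " to ", format(x$dates[length(x$dates)]),
      ", cumulative ", round(x$cumulative[length(x$cumulative)], 1),
      " GDD\n", sep = "")
  invisible(x)
}

# Build a thermal_time_series directly from daily GDD values (no calendar);
# used by toy examples and estimators that work on abstract season days.
#' Thermal-time series from raw daily degree-day values
#'
#' @param tt_d nonnegative daily GDD values, one per season day.
#' @param dates optional dates; defaults to day indices starting April 15.
#' @return A `thermal_time_series`.
#' @export
thermal_time_series <- function(tt_d, dates = NULL) {
  if (any(tt_d < 0)) stop("daily thermal time must be nonnegative")
  if (is.null(dates)) dates <- as.Date("2007-04-15") + seq_along(tt_d) - 1
  structure(list(dates = as.Date(dates), tt_d = as.numeric(tt_d),
                 cumulative = cumsum(as.numeric(tt_d))),
            class = "thermal_time_series")
}
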