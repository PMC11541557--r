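#' Daily sea-surface-temperature series for one site
#'
#' Validated container for a per-site daily SST record, the basis of all
#' thermal metrics. Dates must be strictly increasing at a daily step; short
#' gaps (up to `max_gap` days) are filled by linear interpolation with a
#' warning, longer gaps are an error. Temperatures are checked against a
#' plausible oceanic range (-5 to 40 degC).
#'
#' @param site_id Site identifier (scalar character).
#' @param dates Vector of calendar dates (`Date` or coercible).
#' @param sst Numeric vector of daily SST in degC, same length as `dates`.
#' @param max_gap Longest run of missing days repaired by linear
#'   interpolation; longer gaps abort ingest.
#' @return An object of class `sst_series`: a list with elements `site_id`,
#'   `dates` (gap-free daily `Date` vector) and `sst`.
#' @examples
#' s <- sst_series("reef1", seq(as.Date("2000-01-01"), by = "day", length.out = 10),
#'                 rep(28, 10))
#' @export
sst_series <- function(site_id, dates, sst, max_gap = 3) {
  dates <- as_date(dates)
  sst <- as.numeric(sst)
  if (length(dates) != length(sst)) {
    stopf("dates (%d) and sst (%d) lengths differ", length(dates), length(sst))
  }
  if (anyNA(dates)) stopf("missing dates in series '%s'", site_id)
  if (is.unsorted(dates, strictly = TRUE)) {
    stopf("dates must be strictly increasing for site '%s'", site_id)
  }
  if (anyNA(sst)) stopf("missing sst values for site '%s'", site_id)
  bad <- sst < -5 | sst > 40
  if (any(bad)) {
    stopf("site '%s': %d sst values outside plausible range [-5, 40] degC (first: %s = %.2f)",
          site_id, sum(bad), format(dates[which(bad)[1]]), sst[which(bad)[1]])
  }
  step <- as.integer(diff(dates))
  if (any(step > 1)) {
    if (any(step > max_gap + 1)) {
      i <- which(step > max_gap + 1)[1]
      stopf("site '%s': gap of %d days after %s exceeds max_gap = %d",
            site_id, step[i] - 1L, format(dates[i]), max_gap)
    }
    full <- seq(dates[1], dates[length(dates)], by = "day")
    filled <- approx(as.numeric(dates), sst, xout = as.numeric(full))$y
    warnf("site '%s': interpolated %d missing day(s)", site_id,
          length(full) - length(dates))
    dates <- full
    sst <- filled
  }
  lt <- as.POSIXlt(dates)
  structure(list(site_id = site_id, dates = dates, sst = sst,
                 years = lt$year + 1900L, months = lt$mon + 1L),
            class = "sst_series")
}

#' @export
print.sst_series <- function(x, ...) {
  cat(sprintf("<sst_series> site %s: %d days, %s .. %s, mean %.2f degC\n",
              x$site_id, length(x$sst), format(x$dates[1]),
              format(x$dates[length(x$dates)]), mean(x$sst)))
  invisible(x)
}

# Calendar years/months per day, from the fields stored at ingest (falling
# back to formatting for objects built by hand in older sessions).
.series_years <- function(series) {
  series$years %||% (as.POSIXlt(series$dates)$year + 1900L)
}
.series_months <- function(series) {
  series$months %||% (as.POSIXlt(series$dates)$mon + 1L)
}

# Index of `date` within the series, or NA when outside the record.
.series_index <- function(series, date) {
  i <- as.integer(as_date(date) - series$dates[1]) + 1L
  if (i < 1L || i > length(series$dates)) return(NA_integer_)
  i
}

# Values of `values` (defaults to sst) over the trailing window of
# `window_days` ending on and including `end_date`; errors list missing dates.
.window_values <- function(series, end_date, window_days, values = series$sst,
                           what = "window") {
  end_date <- as_date(end_date)
  i1 <- .series_index(series, end_date - window_days + 1L)
  i2 <- .series_index(series, end_date)
  if (is.na(i1) || is.na(i2)) {
    stopf("site '%s': %s of %d days ending %s not covered (record spans %s .. %s)",
          series$site_id, what, window_days, format(end_date),
          format(series$dates[1]), format(series$dates[length(series$dates)]))
  }
  values[i1:i2]
}

#' Monthly climatology of daily SST over a baseline period
#'
#' Plain monthly means pooled over the baseline years: the mean for calendar
#' month m is the mean of every daily value falling in month m of a baseline
#' year. No satellite-era re-centering is applied.
#'
#' @param series An [sst_series].
#' @param baseline Length-2 integer vector of first and last baseline year
#'   (default `c(1985, 2012)`).
#' @param min_years Minimum number of complete baseline years required;
#'   fewer is an error unless `allow_partial = TRUE`.
#' @param allow_partial Proceed (with a warning) on baseline coverage below
#'   `min_years` complete years.
#' @return Named numeric vector of 12 monthly means (degC), names `"1".."12"`.
#' @export
monthly_climatology <- function(series, baseline = c(1985, 2012),
                                min_years = 20, allow_partial = FALSE) {
  yrs <- .series_years(series)
  keep <- yrs >= baseline[1] & yrs <= baseline[2]
  if (!any(keep)) stopf("site '%s': no data in baseline %d-%d",
                        series$site_id, baseline[1], baseline[2])
  n_complete <- sum(tabulate(yrs[keep] - baseline[1] + 1L,
                             baseline[2] - baseline[1] + 1L) >= 365L)
  if (n_complete < min_years) {
    msg <- sprintf("site '%s': only %d complete baseline years (< %d)",
                   series$site_id, n_complete, min_years)
    if (!allow_partial) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  } else if (n_complete < baseline[2] - baseline[1] + 1L) {
    warnf("site '%s': baseline partially covered (%d/%d complete years)",
          series$site_id, n_complete, baseline[2] - baseline[1] + 1L)
  }
  mo <- .series_months(series)[keep]
  means <- vapply(1:12, function(m) mean(series$sst[keep][mo == m]), 0.0)
  names(means) <- as.character(1:12)
  means
}

#' Maximum monthly mean (MMM)
#'
#' The climatological mean of the hottest calendar month: the bleaching
#' threshold reference of the hotspot and Degree Heating Weeks metrics.
#'
#' @param monthly_mean Numeric vector of 12 monthly climatological means.
#' @return MMM in degC.
#' @export
compute_mmm <- function(monthly_mean) {
  if (length(monthly_mean) != 12 || anyNA(monthly_mean)) {
    stopf("monthly_mean must be 12 finite values (got %d)", length(monthly_mean))
  }
  max(monthly_mean)
}

#' Per-site climatology profile
#'
#' Bundles the monthly climatology, the maximum monthly mean (MMM) and the
#' climatological seasonal warming rate over a baseline period.
#'
#' @inheritParams monthly_climatology
#' @return Object of class `climatology`: list with `site_id`,
#'   `baseline_start`, `baseline_end`, `monthly_mean` (12 values, degC),
#'   `mmm` (degC) and `rotc_clim` (degC per week).
#' @export
climatology <- function(series, baseline = c(1985, 2012), min_years = 20,
                        allow_partial = FALSE) {
  mm <- monthly_climatology(series, baseline, min_years, allow_partial)
  structure(list(site_id = series$site_id,
                 baseline_start = baseline[1],
                 baseline_end = baseline[2],
                 monthly_mean = mm,
                 mmm = compute_mmm(mm),
                 rotc_clim = rotc_clim(series, baseline, min_years,
                                       allow_partial)),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology> site %s (%d-%d): MMM %.3f degC, ROTC_clim %.4f degC/week\n",
              x$site_id, x$baseline_start, x$baseline_end, x$mmm, x$rotc_clim))
  invisible(x)
}
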