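#' Hotspot series: positive daily anomalies above the MMM
#'
#' HS(t) = max(SST(t) - MMM, 0). Hotspots are the building block of every
#' accumulated heat-stress metric (Degree Heating Weeks, HS sums, exceedance
#' counts).
#'
#' @param series An [sst_series].
#' @param mmm Maximum monthly mean in degC (see [compute_mmm]).
#' @return Object of class `hotspot_series`: list with `site_id`, `dates`, `hs`.
#' @export
hotspots <- function(series, mmm) {
  if (!is.finite(mmm)) stopf("mmm must be finite")
  structure(list(site_id = series$site_id, dates = series$dates,
                 hs = pmax(series$sst - mmm, 0)),
            class = "hotspot_series")
}

.hs_window <- function(hs, end_date, window_days, what = "window") {
  .window_values(hs, end_date, window_days, values = hs$hs, what = what)
}

#' Degree Heating Weeks over a trailing window
#'
#' Accumulates hotspots of at least `hs_threshold` (default 1 degC, inclusive)
#' over the trailing `window_days` ending on and including `end_date`, divided
#' by 7 to express the result per week. The conventional satellite product
#' uses an 84-day window; 28- and 555-day variants capture short-term and
#' chronic accumulation.
#'
#' @param hs A `hotspot_series` from [hotspots].
#' @param end_date Last day of the window (inclusive).
#' @param window_days Window length in days (28, 84 or 555 in the standard
#'   metric set).
#' @param hs_threshold Minimum hotspot (degC) counted into the sum.
#' @return DHW in degC-weeks.
#' @export
dhw <- function(hs, end_date, window_days = 84, hs_threshold = 1.0) {
  v <- .hs_window(hs, end_date, window_days, "DHW window")
  sum(v[v >= hs_threshold]) / 7
}

#' Sum of hotspots over a trailing window
#'
#' Unlike [dhw], every positive anomaly counts: no 1 degC threshold and no
#' division by 7. Units degC (summed daily anomalies).
#' @inheritParams dhw
#' @export
hs_sum <- function(hs, end_date, window_days) {
  sum(.hs_window(hs, end_date, window_days, "HS-sum window"))
}

#' Mean hotspot over a trailing window (acute heat stress)
#'
#' @inheritParams dhw
#' @export
hs_mean <- function(hs, end_date, window_days = 3) {
  mean(.hs_window(hs, end_date, window_days, "HS-mean window"))
}

#' Days with hotspots exceeding a threshold in a trailing window
#'
#' Counts days with HS strictly greater than `threshold` (1 or 2 degC in the
#' standard metric set) in the trailing window.
#' @inheritParams dhw
#' @param threshold Exceedance threshold in degC.
#' @return Integer count of days.
#' @export
hs_exceedance_days <- function(hs, end_date, window_days, threshold) {
  sum(.hs_window(hs, end_date, window_days, "HS-exceedance window") > threshold)
}

# Weekly block means for one calendar year: consecutive 7-day blocks anchored
# at 1 January, partial trailing block dropped.
.weekly_means_year <- function(series, year) {
  d1 <- as.Date(sprintf("%d-01-01", year))
  d2 <- as.Date(sprintf("%d-12-31", year))
  i1 <- .series_index(series, d1)
  i2 <- .series_index(series, d2)
  if (is.na(i1) || is.na(i2)) {
    stopf("site '%s': year %d not fully covered", series$site_id, year)
  }
  x <- series$sst[i1:i2]
  nw <- length(x) %/% 7L
  colMeans(matrix(x[seq_len(nw * 7L)], nrow = 7L))
}

.slope <- function(y, x = seq_along(y)) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Annual seasonal warming rate (ROTC)
#'
#' Weekly mean temperatures are computed over consecutive 7-day blocks
#' anchored at 1 January; the year's maximum weekly mean is located and the
#' least-squares slope of weekly mean versus week index over the 12 weeks
#' ending at (and including) the maximum week is returned, in degC per week.
#' This is the rate of temperature change during the roughly three months of
#' seasonal warming preceding the annual thermal peak.
#'
#' @param series An [sst_series] covering the full year.
#' @param year Calendar year.
#' @return Slope in degC per week.
#' @export
rotc_annual <- function(series, year) {
  wm <- .weekly_means_year(series, year)
  if (diff(range(wm)) < 1e-12) return(0)  # no seasonal signal, flat trend
  w <- which.max(wm)
  if (w < 12L) {
    stopf("site '%s', year %d: maximum weekly mean falls in week %d, within the first 12 weeks",
          series$site_id, year, w)
  }
  .slope(wm[(w - 11L):w])
}

#' Climatological seasonal warming rate (ROTC over a baseline)
#'
#' Arithmetic mean of the annual seasonal warming rates ([rotc_annual]) over
#' the baseline years (default 1985-2012).
#'
#' @inheritParams monthly_climatology
#' @return degC per week.
#' @export
rotc_clim <- function(series, baseline = c(1985, 2012), min_years = 20,
                      allow_partial = FALSE) {
  yrs <- .series_years(series)
  counts <- vapply(baseline[1]:baseline[2], function(y) sum(yrs == y), 0L)
  complete <- (baseline[1]:baseline[2])[counts >= 365L]
  if (length(complete) < min_years) {
    msg <- sprintf("site '%s': only %d complete baseline years (< %d) for ROTC",
                   series$site_id, length(complete), min_years)
    if (!allow_partial) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  mean(vapply(complete, function(y) rotc_annual(series, y), 0.0))
}

#' Maximum recent seasonal warming rate before a sampling date
#'
#' For every day d in the 84 days ending at `sample_date`, the trailing 84
#' days ending at d are split into 12 consecutive 7-day blocks and the
#' least-squares slope of the block means versus block index is computed; the
#' maximum slope over the 84 candidate end days is returned. This captures
#' the steepest recent 12-week warming observed before sampling.
#'
#' @param series An [sst_series] with at least 167 days of record ending at
#'   `sample_date`.
#' @param sample_date Sampling date (inclusive end of the scan).
#' @return Maximum slope in degC per week.
#' @export
rotc_recent_max <- function(series, sample_date) {
  sample_date <- as_date(sample_date)
  x <- .window_values(series, sample_date, 167L, what = "ROTC history")
  slopes <- vapply(0:83, function(off) {
    w <- x[(84L - off):(167L - off)]  # 84 days ending at sample_date - off
    .slope(colMeans(matrix(w, nrow = 7L)))
  }, 0.0)
  max(slopes)
}

#' Standard deviation of daily SST over a trailing window
#'
#' Sample standard deviation (n - 1 denominator) of the daily temperatures in
#' the trailing window: a recent thermal variability metric.
#' @inheritParams rotc_recent_max
#' @param window_days Window length in days.
#' @export
sd_window <- function(series, sample_date, window_days = 84) {
  sd(.window_values(series, sample_date, window_days, what = "SD window"))
}

# Daily rolling DHW series (degC-weeks); NA before the first complete window.
.dhw_daily <- function(series, mmm, window_days = 84, hs_threshold = 1.0) {
  h <- pmax(series$sst - mmm, 0)
  h[h < hs_threshold] <- 0
  roll_sum(h, window_days) / 7
}

# Closed-form simple regression slope and intercept.
.lin_fit <- function(y, x) {
  xc <- x - mean(x)
  b <- sum(xc * y) / sum(xc^2)
  c(a = mean(y) - b * mean(x), b = b)
}

# Iterated feasible GLS slope under AR(1) errors (Cochrane-Orcutt): estimate
# rho from OLS residuals, quasi-difference, refit, iterate to convergence.
# Returns NA when the rho estimate is degenerate (|rho| > 0.98) so the caller
# can fall back to OLS.
.gls_ar1_slope <- function(y, x, max_iter = 25, tol = 1e-7) {
  cf <- .lin_fit(y, x)
  rho <- 0
  for (i in seq_len(max_iter)) {
    e <- y - cf[["a"]] - cf[["b"]] * x
    n <- length(e)
    denom <- sum(e[-n]^2)
    rho_new <- if (denom > 0) sum(e[-1] * e[-n]) / denom else 0
    if (!is.finite(rho_new) || abs(rho_new) > 0.98) return(NA_real_)
    ys <- y[-1] - rho_new * y[-n]
    xs <- x[-1] - rho_new * x[-n]
    cfs <- .lin_fit(ys, xs)
    cf <- c(a = cfs[["a"]] / (1 - rho_new), b = cfs[["b"]])
    if (abs(rho_new - rho) < tol) break
    rho <- rho_new
  }
  cf[["b"]]
}

#' Trend of annual maximum Degree Heating Weeks
#'
#' For every year from `start_year` to `end_year`, the maximum over days of
#' the 84-day DHW is computed; a linear trend of annual maximum versus year is
#' then fitted by iterated feasible generalized least squares with AR(1)
#' residual correlation (falling back to ordinary least squares when the AR
#' coefficient estimate is degenerate, |rho| > 0.98). Negative trends are
#' allowed.
#'
#' @param series An [sst_series] covering at least 10 of the requested years.
#' @param mmm Maximum monthly mean in degC.
#' @param start_year,end_year Year range (end_year typically the sampling year).
#' @return Trend slope in degC-weeks per year.
#' @export
dhw_annual_max_trend <- function(series, mmm, start_year = 1985, end_year,
                                 .dd = NULL) {
  yrs <- .series_years(series)
  dd <- .dd %||% .dhw_daily(series, mmm)
  amax <- vapply(start_year:end_year, function(y) {
    v <- dd[yrs == y]
    v <- v[!is.na(v)]
    if (length(v) < 200L) NA_real_ else max(v)
  }, 0.0)
  yr <- (start_year:end_year)[!is.na(amax)]
  amax <- amax[!is.na(amax)]
  if (length(amax) < 10L) {
    stopf("site '%s': only %d complete years for the DHW trend (need >= 10)",
          series$site_id, length(amax))
  }
  slope <- if (sd(amax) == 0) 0 else .gls_ar1_slope(amax, yr)
  if (is.na(slope)) slope <- .lin_fit(amax, yr)[["b"]]
  slope
}

#' Change in maximum DHW relative to the previous year
#'
#' Difference between the maximum daily 84-day DHW observed within the
#' sampling calendar year up to and including `sample_date` (the current
#' event) and the maximum daily DHW over the previous calendar year. Positive
#' values mean the current event is hotter than anything in the previous
#' year.
#'
#' @inheritParams dhw_annual_max_trend
#' @param sample_date Sampling date.
#' @return Difference in degC-weeks.
#' @export
delta_dhw <- function(series, mmm, sample_date, .dd = NULL) {
  sample_date <- as_date(sample_date)
  year <- as.integer(format(sample_date, "%Y"))
  yrs <- .series_years(series)
  dd <- .dd %||% .dhw_daily(series, mmm)
  cur <- dd[yrs == year & series$dates <= sample_date]
  prev <- dd[yrs == year - 1L]
  if (length(prev) < 365L || anyNA(prev) || length(cur) == 0L || anyNA(cur)) {
    stopf("site '%s': need complete DHW coverage of year %d and of %s up to %s",
          series$site_id, year - 1L, year, format(sample_date))
  }
  max(cur) - max(prev)
}

#' All remote-sensing heat-stress metrics at one site and date
#'
#' Evaluates the full set of seventeen thermal exposure and variability
#' metrics for one site at one sampling date: the two climatological
#' indicators (MMM, climatological seasonal warming rate), recent thermal
#' variation (maximum recent warming rate, 84-day SD), acute stress (3-day
#' mean hotspot, exceedance-day counts at 1 and 2 degC over 28 and 84 days),
#' accumulated stress (hotspot sums over 28/84/555 days, DHW over
#' 28/84/555 days) and the two long-term indicators (trend of annual maximum
#' DHW, change in maximum DHW vs the previous year).
#'
#' @param series An [sst_series] spanning the climatology baseline through
#'   `sample_date`.
#' @param profile A [climatology] profile for the same site.
#' @param sample_date Sampling date.
#' @return One-row `data.frame` with columns `site_id`, `sample_date`, `mmm`,
#'   `rotc_clim`, `rotc_84days`, `sd_84days`, `hs_3days`, `hs_28days`,
#'   `hs_84days`, `hs_555days`, `hs1_28days`, `hs1_84days`, `hs2_28days`,
#'   `hs2_84days`, `dhw_28days`, `dhw`, `dhw_555days`, `trend_dhw`,
#'   `delta_dhw`.
#' @export
exposure_metrics <- function(series, profile, sample_date) {
  sample_date <- as_date(sample_date)
  hs <- hotspots(series, profile$mmm)
  dd <- .dhw_daily(series, profile$mmm)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("metric '%s' failed for site '%s' at %s: %s", name,
            series$site_id, format(sample_date), conditionMessage(e))
    })
  }
  data.frame(
    site_id = series$site_id,
    sample_date = sample_date,
    mmm = profile$mmm,
    rotc_clim = profile$rotc_clim,
    rotc_84days = step("rotc_84days", rotc_recent_max(series, sample_date)),
    sd_84days = step("sd_84days", sd_window(series, sample_date, 84)),
    hs_3days = step("hs_3days", hs_mean(hs, sample_date, 3)),
    hs_28days = step("hs_28days", hs_sum(hs, sample_date, 28)),
    hs_84days = step("hs_84days", hs_sum(hs, sample_date, 84)),
    hs_555days = step("hs_555days", hs_sum(hs, sample_date, 555)),
    hs1_28days = step("hs1_28days", hs_exceedance_days(hs, sample_date, 28, 1)),
    hs1_84days = step("hs1_84days", hs_exceedance_days(hs, sample_date, 84, 1)),
    hs2_28days = step("hs2_28days", hs_exceedance_days(hs, sample_date, 28, 2)),
    hs2_84days = step("hs2_84days", hs_exceedance_days(hs, sample_date, 84, 2)),
    dhw_28days = step("dhw_28days", dhw(hs, sample_date, 28)),
    dhw = step("dhw", dhw(hs, sample_date, 84)),
    dhw_555days = step("dhw_555days", dhw(hs, sample_date, 555)),
    trend_dhw = step("trend_dhw",
                     dhw_annual_max_trend(series, profile$mmm,
                                          profile$baseline_start,
                                          as.integer(format(sample_date, "%Y")),
                                          .dd = dd)),
    delta_dhw = step("delta_dhw",
                     delta_dhw(series, profile$mmm, sample_date, .dd = dd)),
    stringsAsFactors = FALSE
  )
}
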