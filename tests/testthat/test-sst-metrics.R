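test_that("series ingest validates dates, range and gaps", {
  d <- seq(as.Date("2000-01-01"), by = "day", length.out = 10)
  expect_error(sst_series("a", rev(d), rep(28, 10)), "strictly increasing")
  expect_error(sst_series("a", d, c(rep(28, 9), 55)), "plausible range")
  # 2-day gap interpolated with a warning
  expect_warning(s <- sst_series("a", d[-c(4, 5)], seq(28, 28.9, length.out = 8)),
                 "interpolated")
  expect_equal(length(s$sst), 10)
  expect_equal(s$sst[4], 28 + 3 * 0.9 / 9, tolerance = 1e-9)
  # 5-day gap is an error
  expect_error(sst_series("a", d[-(3:7)], rep(28, 5)), "gap")
})

test_that("monthly climatology matches constant and sinusoid structure", {
  mc <- monthly_climatology(flat_series(28))
  expect_equal(unname(mc), rep(28, 12), tolerance = 1e-12)
  expect_equal(compute_mmm(mc), 28)

  s <- sinusoid_series(mean_sst = 28, amplitude = 1.5, peak_doy = 258)
  mc <- monthly_climatology(s)
  expect_lt(abs(compute_mmm(mc) - 28), 1.5)
  # hottest month is September (contains day 258), coolest is March
  expect_equal(unname(which.max(mc)), 9L)
  expect_equal(unname(which.min(mc)), 3L)
})

test_that("shifting one baseline year shifts monthly means by 1/n_years", {
  s <- flat_series(28, from = 1985, to = 2012)
  sst2 <- s$sst
  sst2[format(s$dates, "%Y") == "1990"] <- 29
  s2 <- sst_series("s1", s$dates, sst2)
  mc1 <- monthly_climatology(s, baseline = c(1985, 2012))
  mc2 <- monthly_climatology(s2, baseline = c(1985, 2012))
  # brute-force expectation: the shifted year contributes its share of the
  # pooled daily values (month lengths vary with leap years)
  mo_all <- as.integer(format(s$dates, "%m"))
  mo_1990 <- mo_all[format(s$dates, "%Y") == "1990"]
  expected <- vapply(1:12, function(m) sum(mo_1990 == m) / sum(mo_all == m), 0.0)
  expect_equal(unname(mc2 - mc1), expected, tolerance = 1e-9)
})

test_that("baseline coverage below the floor is an error unless overridden", {
  s <- flat_series(28, from = 2000, to = 2012)
  expect_error(monthly_climatology(s, baseline = c(1985, 2012)), "complete baseline years")
  expect_warning(mc <- monthly_climatology(s, baseline = c(1985, 2012),
                                           allow_partial = TRUE))
  expect_equal(unname(mc), rep(28, 12))
})

test_that("hotspots clamp at zero and match the definition elementwise", {
  s <- make_series(c(30.2, 28.5, 29.0))
  h <- hotspots(s, 29.0)
  expect_equal(h$hs, c(1.2, 0, 0), tolerance = 1e-12)
  set.seed(42)
  s2 <- make_series(runif(300, 26, 31))
  h2 <- hotspots(s2, 28.5)
  expect_true(all(h2$hs >= 0))
  expect_identical(h2$hs == 0, s2$sst <= 28.5)
})

test_that("DHW matches its analytic values and a brute-force oracle", {
  base <- flat_series(28, from = 2010, to = 2012)
  # hotspot exactly 1.0 everywhere
  h1 <- hotspots(base, 27.0)
  expect_identical(dhw(h1, as.Date("2012-10-01")), 12)
  # 0.9 degC hotspots fall below the inclusive 1 degC threshold
  h09 <- hotspots(base, 27.1)
  expect_identical(dhw(h09, as.Date("2012-10-01")), 0)
  # 14 days of hs = 2.0 inside the window
  x <- rep(28, 400)
  x[200:213] <- 30
  s <- make_series(x, start = "2011-01-01")
  h <- hotspots(s, 28)
  expect_equal(dhw(h, s$dates[240]), 4, tolerance = 1e-12)
  # random pattern equals loop oracle to machine precision
  set.seed(7)
  s3 <- make_series(runif(700, 27, 31), start = "2010-01-01")
  h3 <- hotspots(s3, 28.8)
  for (end in s3$dates[c(600, 650, 700)]) {
    expect_equal(dhw(h3, end, 84), bf_dhw(h3, end, 84), tolerance = 1e-12)
    expect_equal(hs_sum(h3, end, 28), sum(bf_window(h3, end, 28)), tolerance = 1e-12)
    expect_equal(hs_mean(h3, end, 3), mean(bf_window(h3, end, 3)), tolerance = 1e-12)
  }
})

test_that("incomplete windows raise errors naming the coverage", {
  s <- make_series(rep(28, 100))
  h <- hotspots(s, 27)
  expect_error(dhw(h, s$dates[50], 84), "not covered")
  expect_error(hs_sum(h, s$dates[1] - 1, 28), "not covered")
})

test_that("exceedance-day counts are integers, bounded, and monotone in threshold", {
  x <- rep(28, 100)
  x[90:94] <- 29.5
  h <- hotspots(make_series(x), 28)
  expect_identical(hs_exceedance_days(h, make_series(x)$dates[100], 28, 1), 5L)
  expect_identical(hs_exceedance_days(h, make_series(x)$dates[100], 28, 2), 0L)
  set.seed(11)
  s <- make_series(runif(200, 27, 32))
  h <- hotspots(s, 28.5)
  for (w in c(28, 84)) {
    c1 <- hs_exceedance_days(h, s$dates[200], w, 1)
    c2 <- hs_exceedance_days(h, s$dates[200], w, 2)
    expect_lte(c2, c1)
    expect_lte(c1, w)
  }
})

test_that("ROTC is exact on ramps and zero on constants", {
  doy_ramp <- flat_series(28, from = 2000, to = 2000)
  x <- 25 + 0.03 * seq_along(doy_ramp$dates)
  ramp <- sst_series("r", doy_ramp$dates, x)
  expect_equal(rotc_annual(ramp, 2000), 0.21, tolerance = 1e-9)
  expect_equal(rotc_annual(flat_series(28, 2000, 2000), 2000), 0)
  # recent-max scan on the same ramp
  long <- make_series(20 + 0.03 * seq_len(400), start = "2000-01-01")
  expect_equal(rotc_recent_max(long, long$dates[400]), 0.21, tolerance = 1e-9)
  expect_equal(rotc_recent_max(flat_series(28, 2000, 2001),
                               as.Date("2001-12-01")), 0)
})

test_that("ROTC matches an independent weekly-means regression oracle", {
  s <- sinusoid_series(amplitude = 2.5, noise_sd = 0.2, seed = 3,
                       from = 2000, to = 2000)
  # oracle: explicit weekly means and lm fit
  wm <- vapply(seq_len(52), function(w) mean(s$sst[(7 * w - 6):(7 * w)]), 0.0)
  w <- which.max(wm)
  fit <- lm(y ~ x, data.frame(y = wm[(w - 11):w], x = 1:12))
  expect_equal(rotc_annual(s, 2000), unname(coef(fit)[2]), tolerance = 1e-9)
})

test_that("recent-max ROTC equals an exhaustive scan oracle on piecewise series", {
  set.seed(5)
  x <- c(rep(27, 100), 27 + cumsum(runif(150, 0, 0.06)), rep(31, 150))
  s <- make_series(pmin(x, 35), start = "2001-01-01")
  end <- s$dates[380]
  oracle <- max(vapply(0:83, function(off) {
    idx <- (380 - off - 83):(380 - off)
    wm <- vapply(seq_len(12), function(b) mean(s$sst[idx[(7 * b - 6):(7 * b)]]), 0.0)
    unname(coef(lm(wm ~ I(1:12)))[2])
  }, 0.0))
  expect_equal(rotc_recent_max(s, end), oracle, tolerance = 1e-9)
})

test_that("climatological ROTC averages the annual rates", {
  s <- sinusoid_series(from = 1984, to = 2013)
  annual <- rotc_annual(s, 1990)
  expect_equal(rotc_clim(s, c(1985, 2012)), annual, tolerance = 1e-10)
})

test_that("windowed SD matches closed forms and is translation invariant", {
  expect_equal(sd_window(flat_series(28, 2000, 2001), as.Date("2001-06-01")), 0)
  x <- rep(c(28, 30), 60)
  s <- make_series(x)
  v <- sd_window(s, s$dates[84], 84)
  expect_equal(v, sqrt(84 / 83), tolerance = 1e-12)  # two-point closed form
  s2 <- make_series(x + 3.3)
  expect_equal(sd_window(s2, s2$dates[84], 84), v, tolerance = 1e-12)
})

test_that("DHW annual-maximum trend is exact on linear maxima and zero on constants", {
  base <- flat_series(26, from = 1985, to = 1996)
  x <- base$sst
  # per year k, a block of 7k days at hotspot 2 degC -> annual max DHW = 2k
  # (all blocks fit inside one 84-day window since 7k <= 84)
  for (k in seq_len(12)) {
    y0 <- which(format(base$dates, "%Y") == as.character(1984 + k))[150]
    x[y0:(y0 + 7 * k - 1)] <- 28
  }
  s <- sst_series("s1", base$dates, x)
  expect_equal(dhw_annual_max_trend(s, 26, 1985, 1996), 2, tolerance = 1e-6)
  expect_equal(dhw_annual_max_trend(flat_series(28, 1985, 2000), 27.5,
                                    1985, 2000), 0)
  expect_error(dhw_annual_max_trend(flat_series(28, 1995, 2000), 27.5,
                                    1995, 2000), ">= 10")
})

test_that("AR(1) feasible GLS recovers a known trend across replicates", {
  set.seed(99)
  n <- 30
  slopes <- replicate(200, {
    e <- as.numeric(filter(rnorm(n, sd = 0.4), 0.5, method = "recursive"))
    reefheat:::.gls_ar1_slope(0.1 * (1:n) + e, 1:n)
  })
  slopes <- slopes[!is.na(slopes)]
  expect_gt(length(slopes), 180)
  expect_lt(abs(mean(slopes) - 0.1), 0.02)
  expect_gte(mean(abs(slopes - 0.1) < 3 * sd(slopes)), 0.95)
})

test_that("delta DHW follows the current-minus-previous sign convention", {
  base <- flat_series(26, from = 2014, to = 2016)
  x <- base$sst
  yr16 <- which(format(base$dates, "%Y") == "2016")
  yr15 <- which(format(base$dates, "%Y") == "2015")
  x[yr16[200:227]] <- 28.5   # current year: dhw max = 2.5*28/7 = 10
  x[yr15[200:213]] <- 27.5   # previous year: dhw max = 1.5*14/7 = 3
  s <- sst_series("s1", base$dates, x)
  d <- delta_dhw(s, 26, base$dates[yr16[260]])
  expect_equal(d, 10 - 3, tolerance = 1e-9)
  # identical years cancel
  expect_equal(delta_dhw(flat_series(28, 2014, 2016), 27.5,
                         as.Date("2016-10-01")), 0)
  # previous year hotter gives a negative value
  x2 <- base$sst
  x2[yr15[200:227]] <- 28.5
  s2 <- sst_series("s1", base$dates, x2)
  expect_lt(delta_dhw(s2, 26, base$dates[yr16[260]]), 0)
})

test_that("exposure metrics bundle is complete, finite and respects invariants", {
  tmpl <- site_templates(2, seed = 8)[1, ]
  s <- gen_sst(tmpl, 1985:2016, seed = 2,
               events = data.frame(start = as.Date("2016-08-10"),
                                   length = 40, peak = 2))
  cl <- climatology(s)
  em <- exposure_metrics(s, cl, as.Date("2016-10-10"))
  num <- unlist(em[-(1:2)])
  expect_length(num, 17)
  expect_true(all(is.finite(num)))
  expect_true(all(em[c("hs_3days", "hs_28days", "hs_84days", "hs_555days",
                       "hs1_28days", "hs1_84days", "hs2_28days", "hs2_84days",
                       "dhw_28days", "dhw", "dhw_555days")] >= 0))
  expect_lte(em$dhw_28days, em$dhw)
  expect_lte(em$dhw, em$dhw_555days)
  # a zero-anomaly record zeroes the whole hotspot family
  cl2 <- climatology(flat_series(28, 1984, 2016))
  em2 <- exposure_metrics(flat_series(28, 1984, 2016), cl2, as.Date("2016-10-10"))
  expect_equal(unname(unlist(em2[c("hs_3days", "hs_28days", "hs_555days",
                                   "dhw", "trend_dhw", "delta_dhw")])),
               rep(0, 6))
})

test_that("hotspot metrics are invariant to joint translation of series and MMM", {
  set.seed(21)
  s <- make_series(runif(700, 27, 31), start = "2010-01-01")
  for (shift in c(-2, 3.7)) {
    s2 <- make_series(s$sst + shift, start = "2010-01-01")
    h1 <- hotspots(s, 28.5)
    h2 <- hotspots(s2, 28.5 + shift)
    end <- s$dates[700]
    expect_equal(dhw(h1, end), dhw(h2, end), tolerance = 1e-10)
    expect_equal(hs_sum(h1, end, 84), hs_sum(h2, end, 84), tolerance = 1e-10)
    expect_identical(hs_exceedance_days(h1, end, 84, 1),
                     hs_exceedance_days(h2, end, 84, 1))
  }
})

test_that("raising a single day's temperature never decreases hotspot metrics", {
  set.seed(31)
  s <- make_series(runif(700, 27, 31), start = "2010-01-01")
  end <- s$dates[700]
  h0 <- hotspots(s, 28.5)
  base <- c(dhw(h0, end), hs_sum(h0, end, 84), hs_mean(h0, end, 3),
            hs_exceedance_days(h0, end, 84, 1))
  for (i in c(650, 690, 700)) {
    x <- s$sst
    x[i] <- x[i] + 1.5
    h <- hotspots(make_series(pmin(x, 40), start = "2010-01-01"), 28.5)
    after <- c(dhw(h, end), hs_sum(h, end, 84), hs_mean(h, end, 3),
               hs_exceedance_days(h, end, 84, 1))
    expect_true(all(after >= base - 1e-12))
  }
})
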