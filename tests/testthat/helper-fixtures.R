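# Shared builders and independent oracles for the test suite.

# Daily series starting at `start` with the given temperatures.
make_series <- function(sst, start = "2000-01-01", site = "s1") {
  sst_series(site, seq(as.Date(start), by = "day", length.out = length(sst)), sst)
}

# A constant-temperature series spanning whole calendar years.
flat_series <- function(value = 28, from = 1984, to = 2016, site = "s1") {
  dates <- seq(as.Date(sprintf("%d-01-01", from)),
               as.Date(sprintf("%d-12-31", to)), by = "day")
  sst_series(site, dates, rep(value, length(dates)))
}

# Sinusoidal annual cycle (peak at day-of-year `peak_doy`) plus optional noise.
sinusoid_series <- function(mean_sst = 28, amplitude = 1.5, peak_doy = 258,
                            from = 1984, to = 2016, noise_sd = 0, seed = 1,
                            site = "s1") {
  dates <- seq(as.Date(sprintf("%d-01-01", from)),
               as.Date(sprintf("%d-12-31", to)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  x <- mean_sst + amplitude * cos(2 * pi * (doy - peak_doy) / 365)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(length(x), sd = noise_sd)
  }
  sst_series(site, dates, x)
}

# Brute-force trailing-window oracle over a hotspot series: loops over dates.
bf_window <- function(hs_obj, end_date, window_days) {
  days <- seq(as.Date(end_date) - window_days + 1, as.Date(end_date), by = "day")
  vapply(days, function(d) hs_obj$hs[which(hs_obj$dates == d)], 0.0)
}

bf_dhw <- function(hs_obj, end_date, window_days = 84, threshold = 1) {
  v <- bf_window(hs_obj, end_date, window_days)
  s <- 0
  for (x in v) if (x >= threshold) s <- s + x
  s / 7
}

# Eigen-decomposition correspondence analysis, first-axis row scores.
ca_axis1_oracle <- function(M) {
  P <- M / sum(M)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  sv$u[, 1] / sqrt(r)
}

# Unimodal community matrix along a known 1-D gradient.
gradient_community <- function(n_sites = 30, n_species = 20, seed = 1) {
  set.seed(seed)
  g <- seq(0, 10, length.out = n_sites)
  opt <- runif(n_species, 0, 10)
  tol <- runif(n_species, 1, 2.5)
  M <- sapply(seq_len(n_species), function(k) {
    100 * exp(-(g - opt[k])^2 / (2 * tol[k]^2))
  })
  rownames(M) <- paste0("site", seq_len(n_sites))
  colnames(M) <- paste0("sp", seq_len(n_species))
  list(comm = M, gradient = g)
}

# Tiny colony table.
colonies_df <- function(species, category, count) {
  data.frame(species = species, category = category, count = count,
             stringsAsFactors = FALSE)
}

# A fast boosted-model configuration for mechanical unit tests (the full
# protocol configuration is exercised in the acceptance tests).
fast_config <- function(seed = 1) {
  model_config(learning_rates = c(0.05, 0.02), tree_depths = c(2, 3),
               min_trees = 60, k_folds = 5, max_trees = 800, seed = seed)
}
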