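#' Caribbean coral species pool for synthetic communities
#'
#' Forty scleractinian species commonly recorded on western Caribbean reefs,
#' used as the sampling pool of the community generator. Purely a name pool:
#' the synthetic sensitivity and functional values attached to these names by
#' the generators are simulated, not measured.
#' @return Character vector of species names.
#' @export
coral_species_pool <- function() {
  c("Agaricia agaricites", "Agaricia tenuifolia", "Agaricia humilis",
    "Agaricia lamarcki", "Acropora palmata", "Acropora cervicornis",
    "Orbicella annularis", "Orbicella faveolata", "Orbicella franksi",
    "Montastraea cavernosa", "Siderastrea siderea", "Siderastrea radians",
    "Porites astreoides", "Porites porites", "Porites furcata",
    "Porites divaricata", "Pseudodiploria strigosa", "Pseudodiploria clivosa",
    "Diploria labyrinthiformis", "Colpophyllia natans", "Dichocoenia stokesii",
    "Dendrogyra cylindrus", "Eusmilia fastigiata", "Favia fragum",
    "Isophyllia sinuosa", "Isophyllia rigida", "Madracis decactis",
    "Madracis auretenra", "Manicina areolata", "Meandrina meandrites",
    "Mussa angulosa", "Mycetophyllia lamarckiana", "Mycetophyllia ferox",
    "Oculina diffusa", "Scolymia cubensis", "Solenastrea bournoni",
    "Solenastrea hyades", "Stephanocoenia intersepta", "Helioseris cucullata",
    "Isopora spp")
}

#' Synthetic species bleaching sensitivities
#'
#' Draws a true per-species bleaching sensitivity (expected severity score on
#' `[0, 1]`) for every species in the pool, from a right-skewed distribution
#' spanning roughly 0.05-0.6 as observed across Caribbean assemblages.
#'
#' @param species_pool Character vector of species.
#' @param seed Seed.
#' @return Named numeric vector of sensitivities in `(0, 1)`.
#' @export
species_sensitivity_profile <- function(species_pool = coral_species_pool(),
                                        seed = NULL) {
  with_seed(seed, {
    setNames(0.05 + 0.55 * rbeta(length(species_pool), 2, 4), species_pool)
  })
}

#' Synthetic functional coefficient table
#'
#' Simulated morphology/growth functional coefficients for the species pool
#' (log-normally spread around 0.45, the order of magnitude of published reef
#' functional indices).
#'
#' @inheritParams species_sensitivity_profile
#' @return `data.frame` with columns `species`, `fc`.
#' @export
synthetic_fc_table <- function(species_pool = coral_species_pool(),
                               seed = NULL) {
  with_seed(seed, {
    data.frame(species = species_pool,
               fc = round(exp(rnorm(length(species_pool), log(0.45), 0.35)), 4),
               stringsAsFactors = FALSE)
  })
}

#' Site templates along a synthetic coastline arc
#'
#' Lays `n_sites` reef sites along a ~1000 km coastline arc with
#' log-uniform (1-100 km) along-shore spacing, and draws per-site physical
#' parameters: depth uniform over the observed 1.00-26.45 m range, a
#' seasonal sinusoid (mean and amplitude calibrated so that the resulting
#' climatological maximum monthly mean and seasonal warming rate fall in the
#' ranges typical of the western Caribbean), a warming trend, and red-noise
#' parameters for daily anomalies.
#'
#' @param n_sites Number of sites.
#' @param seed Seed.
#' @return `data.frame` with one row per site: `site_id`, `lat`, `lon`,
#'   `depth`, `mean_sst`, `seasonal_amplitude`, `peak_doy`, `warming_trend`
#'   (degC per decade), `ar1_rho`, `noise_sd`.
#' @export
site_templates <- function(n_sites = 90, seed = NULL) {
  with_seed(seed, {
    gaps <- exp(runif(n_sites - 1, log(1), log(100)))
    s <- c(0, cumsum(gaps))
    s <- s / max(s) * 1000
    amp <- runif(n_sites, 2.70, 3.08)
    mmm_target <- runif(n_sites, 28.66, 28.90)
    data.frame(
      site_id = sprintf("site_%03d", seq_len(n_sites)),
      lat = 21.3 - s / 111,
      lon = -86.7 - 0.25 * sin(pi * s / 1000),
      depth = runif(n_sites, 1.0, 26.45),
      mean_sst = mmm_target - 0.988 * amp,
      seasonal_amplitude = amp,
      peak_doy = 258 + round(runif(n_sites, -4, 4)),
      warming_trend = runif(n_sites, 0.05, 0.15),
      ar1_rho = 0.8,
      noise_sd = 0.3,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a daily SST series for one site
#'
#' Daily SST is the sum of a site mean, a linear warming trend (centered on
#' the 1985-2012 baseline midpoint), an annual sinusoid peaking at
#' `peak_doy`, AR(1) daily anomalies, and optional injected heat events
#' (half-sine anomaly pulses). Deterministic given the seed.
#'
#' @param template One row of [site_templates] (data.frame or list).
#' @param years Integer vector of calendar years to cover (contiguous).
#' @param seed Seed for the AR(1) noise.
#' @param events Optional `data.frame` of heat events with columns `start`
#'   (`Date`), `length` (days) and `peak` (degC added at the event midpoint).
#' @return An [sst_series].
#' @export
gen_sst <- function(template, years, seed = NULL, events = NULL) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  dec <- as.numeric(dates - as.Date("1998-12-31")) / 3652.5
  base <- template$mean_sst + template$warming_trend * dec +
    template$seasonal_amplitude * cos(2 * pi * (doy - template$peak_doy) / 365)
  noise <- with_seed(seed, {
    innov <- rnorm(length(dates),
                   sd = template$noise_sd * sqrt(1 - template$ar1_rho^2))
    as.numeric(filter(innov, template$ar1_rho, method = "recursive"))
  })
  sst <- base + noise
  if (!is.null(events) && nrow(events)) {
    for (k in seq_len(nrow(events))) {
      i0 <- as.integer(as_date(events$start[k]) - dates[1]) + 1L
      len <- events$length[k]
      if (i0 < 1L || i0 > length(dates)) next
      idx <- i0:min(i0 + len - 1L, length(dates))
      u <- (seq_along(idx) - 0.5) / len
      sst[idx] <- sst[idx] + events$peak[k] * sin(pi * u)
    }
  }
  sst_series(template$site_id, dates, sst)
}

#' Generate a community of relative abundances
#'
#' Draws `n_species` species from the pool and symmetric-Dirichlet relative
#' abundances over them; small concentrations give dominance-structured
#' communities, large concentrations approach evenness.
#'
#' @param n_species Number of species (1 to pool size).
#' @param concentration Symmetric Dirichlet parameter (default 1.5).
#' @param species_pool Pool to draw from.
#' @param seed Seed.
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
gen_community <- function(n_species, concentration = 1.5,
                          species_pool = coral_species_pool(), seed = NULL) {
  if (n_species < 1 || n_species > length(species_pool)) {
    stopf("n_species must be in 1..%d", length(species_pool))
  }
  with_seed(seed, {
    sp <- sample(species_pool, n_species)
    g <- rgamma(n_species, shape = concentration)
    if (sum(g) <= 0) g <- rep(1, n_species)
    setNames(g / sum(g), sp)
  })
}

#' Generate one colony-level bleaching survey
#'
#' Colonies are assigned to species by a multinomial draw on the community
#' abundances; each colony's response category (normal/pale/partially/fully
#' bleached, severity scores 0-3) is drawn as Binomial(3, s) where the latent
#' severity `s = plogis(gamma * (qlogis(sens) - center) + eta)` combines the
#' species sensitivity with the site-level driver signal `eta`. The
#' Binomial(3, s) category law makes the expected per-colony severity score
#' equal `s` exactly, so the survey's expected bleaching severity index is
#' the abundance-weighted mean of the species latent severities.
#'
#' @param community Named relative abundances (see [gen_community]).
#' @param sensitivities Named species sensitivities on `(0, 1)`.
#' @param eta Site-level latent signal on the logit scale.
#' @param gamma Strength of the species-sensitivity differentiation.
#' @param center Logit-scale value the sensitivities are centered on
#'   (default 0, i.e. raw `qlogis(sens)`).
#' @param n_colonies Total colonies surveyed (field protocol targets
#'   150-200).
#' @param seed Seed.
#' @return `data.frame` with columns `species`, `category`, `count`.
#' @export
gen_survey <- function(community, sensitivities, eta = 0, gamma = 1,
                       center = 0, n_colonies = 175, seed = NULL) {
  miss <- setdiff(names(community), names(sensitivities))
  if (length(miss)) stopf("no sensitivity for species: %s",
                          paste(miss, collapse = ", "))
  cats <- names(bleach_categories())
  with_seed(seed, {
    counts <- as.integer(rmultinom(1, n_colonies, community))
    rows <- lapply(which(counts > 0), function(k) {
      sp <- names(community)[k]
      s <- plogis(gamma * (qlogis(sensitivities[[sp]]) - center) + eta)
      score <- rbinom(counts[k], 3, s)
      tab <- tabulate(score + 1L, 4L)
      data.frame(species = sp, category = cats[tab > 0],
                 count = tab[tab > 0], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# Metrics usable as true drivers of the generative model.
.driver_vocabulary <- function() {
  c("mmm", "rotc_clim", "rotc_84days", "sd_84days", "hs_3days", "hs_28days",
    "hs_84days", "hs_555days", "hs1_28days", "hs1_84days", "hs2_28days",
    "hs2_84days", "dhw_28days", "dhw", "dhw_555days", "trend_dhw",
    "delta_dhw", "depth", "diversity_n1", "richness", "si_reef")
}

# Calibrate the latent noise sd so the population R2 of the severity index on
# the true drivers hits the target. The expected site severity is the
# community-weighted logistic mixture; colony sampling noise is included
# analytically. Vectorized over a flattened (observation, species) layout:
# w_flat weights, g_flat species logit offsets, idx_obs observation index.
.calibrate_sigma <- function(w_flat, g_flat, idx_obs, eta, target_r2,
                             n_colonies = 175, reps = 200, max_iter = 40,
                             seed = NULL) {
  n_obs <- length(eta)
  eps0 <- with_seed(seed, matrix(rnorm(n_obs * reps), ncol = reps))
  r2_at <- function(sigma) {
    e <- eta + sigma * eps0                     # n_obs x reps
    s <- plogis(g_flat + e[idx_obs, , drop = FALSE])
    sbar <- rowsum(w_flat * s, idx_obs)         # n_obs x reps expected severity
    m <- rowMeans(sbar)
    v_eps <- mean(apply(sbar, 1, var))
    v_col <- mean(sbar * (1 - sbar) / 3) / n_colonies
    var(m) / (var(m) + v_eps + v_col)
  }
  lo <- 1e-3; hi <- 4
  r_lo <- r2_at(lo); r_hi <- r2_at(hi)
  if (target_r2 > r_lo || target_r2 < r_hi) {
    stopf("cannot calibrate latent noise: target R2 %.2f outside achievable [%.3f, %.3f]",
          target_r2, r_hi, r_lo)
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    r <- r2_at(mid)
    if (abs(r - target_r2) < 0.01) return(list(sigma = mid, achieved = r))
    if (r > target_r2) lo <- mid else hi <- mid
  }
  list(sigma = mid, achieved = r)
}

#' Generate a full synthetic bleaching study with known driver structure
#'
#' Builds an end-to-end dataset emulating a multi-year regional bleaching
#' survey: coastline sites with daily SST from 1985 through the last survey
#' year (seasonal cycle, warming trend, AR(1) anomalies, injected heat
#' events escalating over the survey years plus occasional historical
#' events), per-site coral communities, and colony-level surveys whose latent
#' severity is a logistic function of the chosen true drivers. The latent
#' noise is calibrated at generation time so that the population R2 of the
#' severity index on the true drivers matches `generative_r2` (within about
#' 0.02). Everything is reproducible from `seed`.
#'
#' @param n_sites Number of sites (each surveyed every year).
#' @param years Survey years (surveys fall in October-November).
#' @param true_drivers Named numeric vector of logit-scale coefficients on
#'   the z-scored drivers; names from the metric vocabulary (the seventeen
#'   thermal metrics plus `depth`, `diversity_n1`, `richness`, `si_reef`).
#' @param generative_r2 Target population R2 of severity on the true drivers
#'   (0 gives a signal-free dataset).
#' @param gamma Species-sensitivity differentiation strength.
#' @param beta0 Latent intercept (logit scale); default places mean severity
#'   near 0.3.
#' @param seed Seed; all internal randomness derives from it.
#' @param baseline Climatology baseline years.
#' @return List of class `reef_dataset`: `surveys` (tidy colony table:
#'   `site_id`, `date`, `lat`, `lon`, `depth_m`, `species`, `category`,
#'   `count`), `sst` (named list of [sst_series]), `sites` (template table),
#'   `metrics` (per observation: the seventeen thermal metrics already
#'   evaluated), `ground_truth` (true drivers, coefficients, latent noise sd,
#'   achieved R2, species sensitivities, per-observation latent signal).
#' @export
gen_dataset <- function(n_sites = 90, years = 2015:2017,
                        true_drivers = c(rotc_clim = -0.8, hs_28days = 0.8,
                                         si_reef = 0.8),
                        generative_r2 = 0.75, gamma = 1, beta0 = NULL,
                        seed = 1, baseline = c(1985, 2012)) {
  bad <- setdiff(names(true_drivers), .driver_vocabulary())
  if (length(bad)) stopf("unknown driver(s): %s", paste(bad, collapse = ", "))
  beta0 <- beta0 %||% qlogis(0.3)
  sites <- site_templates(n_sites, seed = child_seed(seed, 1))
  pool <- coral_species_pool()
  sens <- species_sensitivity_profile(pool, seed = child_seed(seed, 2))

  # per-site heat events: escalating survey-year events + sparse history
  peak_lo <- c(0.9, 1.1, 1.5)
  peak_hi <- c(1.9, 2.1, 2.5)
  ev_all <- with_seed(child_seed(seed, 3), {
    lapply(seq_len(n_sites), function(i) {
      evs <- lapply(seq_along(years), function(j) {
        data.frame(start = as.Date(sprintf("%d-08-01", years[j])) +
                     round(runif(1, 0, 25)),
                   length = round(runif(1, 40, 70)),
                   peak = runif(1, peak_lo[min(j, 3)], peak_hi[min(j, 3)]))
      })
      hist_years <- (1995:(min(years) - 1))
      hist_years <- hist_years[runif(length(hist_years)) < 0.2]
      if (length(hist_years)) {
        evs <- c(evs, lapply(hist_years, function(y) {
          data.frame(start = as.Date(sprintf("%d-08-15", y)) +
                       round(runif(1, 0, 20)),
                     length = round(runif(1, 30, 60)),
                     peak = runif(1, 0.5, 1.5))
        }))
      }
      do.call(rbind, evs)
    })
  })

  sst <- lapply(seq_len(n_sites), function(i) {
    gen_sst(sites[i, ], years = baseline[1]:max(years),
            seed = child_seed(seed, 100 + i), events = ev_all[[i]])
  })
  names(sst) <- sites$site_id

  communities <- with_seed(child_seed(seed, 4), {
    lapply(seq_len(n_sites), function(i) {
      gen_community(sample(5:34, 1), concentration = 1.5, species_pool = pool)
    })
  })
  names(communities) <- sites$site_id

  sample_dates <- with_seed(child_seed(seed, 5), {
    lapply(years, function(y) {
      as.Date(sprintf("%d-10-01", y)) + round(runif(n_sites, 0, 60))
    })
  })

  # thermal metrics per site x year
  metrics <- vector("list", n_sites * length(years))
  prof <- lapply(seq_len(n_sites), function(i) climatology(sst[[i]], baseline))
  k <- 0
  for (j in seq_along(years)) {
    for (i in seq_len(n_sites)) {
      k <- k + 1
      metrics[[k]] <- exposure_metrics(sst[[i]], prof[[i]], sample_dates[[j]][i])
    }
  }
  metrics <- do.call(rbind, metrics)

  # driver table on the observation level
  wsens <- vapply(communities, function(cm) sum(cm * sens[names(cm)]), 0.0)
  drv <- metrics
  drv$depth <- rep(sites$depth, times = length(years))
  drv$diversity_n1 <- rep(vapply(communities, hill_n1, 0.0), times = length(years))
  drv$richness <- rep(vapply(communities, function(cm) sum(cm > 0), 0.0),
                      times = length(years))
  drv$si_reef <- rep(wsens, times = length(years))
  zz <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  eta <- rep(beta0, nrow(drv))
  for (d in names(true_drivers)) {
    eta <- eta + true_drivers[[d]] * zz(drv[[d]])
  }

  site_of_obs <- match(drv$site_id, sites$site_id)
  centers <- qlogis(pmin(pmax(wsens, 1e-6), 1 - 1e-6))
  flat <- lapply(seq_len(nrow(drv)), function(o) {
    i <- site_of_obs[o]
    cm <- communities[[i]]
    list(w = as.numeric(cm),
         g = gamma * (qlogis(sens[names(cm)]) - centers[i]),
         idx = rep(o, length(cm)))
  })
  w_flat <- unlist(lapply(flat, `[[`, "w"))
  g_flat <- unlist(lapply(flat, `[[`, "g"))
  idx_obs <- unlist(lapply(flat, `[[`, "idx"))

  if (generative_r2 <= 0.01) {
    eta <- rep(beta0, nrow(drv))
    calib <- list(sigma = 0.5, achieved = 0)
    true_drivers[] <- 0
  } else {
    calib <- .calibrate_sigma(w_flat, g_flat, idx_obs, eta, generative_r2,
                              seed = child_seed(seed, 6))
  }

  surveys <- with_seed(child_seed(seed, 7), {
    eps <- rnorm(nrow(drv), sd = calib$sigma)
    nc <- sample(150:200, nrow(drv), replace = TRUE)
    out <- vector("list", nrow(drv))
    for (o in seq_len(nrow(drv))) {
      i <- site_of_obs[o]
      sv <- gen_survey(communities[[i]], sens, eta = eta[o] + eps[o],
                       gamma = gamma, center = centers[i], n_colonies = nc[o])
      sv$site_id <- drv$site_id[o]
      sv$date <- drv$sample_date[o]
      sv$lat <- sites$lat[i]
      sv$lon <- sites$lon[i]
      sv$depth_m <- sites$depth[i]
      out[[o]] <- sv[, c("site_id", "date", "lat", "lon", "depth_m",
                         "species", "category", "count")]
    }
    do.call(rbind, out)
  })

  structure(list(
    surveys = surveys, sst = sst, sites = sites, metrics = metrics,
    ground_truth = list(true_drivers = true_drivers, gamma = gamma,
                        beta0 = beta0, sigma_eps = calib$sigma,
                        generative_r2 = generative_r2,
                        achieved_r2 = calib$achieved,
                        species_sensitivity = sens, eta = eta, seed = seed)
  ), class = "reef_dataset")
}

#' @export
print.reef_dataset <- function(x, ...) {
  cat(sprintf("<reef_dataset> %d sites x %d years, %d colony rows; true drivers: %s (target R2 %.2f)\n",
              nrow(x$sites), length(unique(format(as_date(x$surveys$date), "%Y"))),
              nrow(x$surveys),
              paste(names(x$ground_truth$true_drivers), collapse = ", "),
              x$ground_truth$generative_r2))
  invisible(x)
}
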