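---
title: "Methods: coral bleaching vulnerability from heat stress and reef sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coral bleaching vulnerability from heat stress and reef sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mass coral bleaching is driven by accumulated heat stress, but reefs exposed
to the same stress bleach very differently: the thermal history of a site and
the intrinsic sensitivity of its coral community modulate the response.
`reefheat` implements a desk-scale version of a regional vulnerability
analysis: it derives heat-stress and thermal-variability metrics from daily
sea-surface temperature (SST) records, derives sensitivity metrics from
colony-level bleaching surveys, and identifies which of these metrics drive
the spatial variation of bleaching severity with gradient-boosted regression
trees, including the model-simplification, partial-dependence, interaction
and spatial-autocorrelation diagnostics that such an analysis needs.

Because regional survey data of this kind are rarely redistributable, the
package ships a synthetic-data generator with known ground truth
(`gen_dataset()`). Every stage of the pipeline is validated against it; the
generator is first-class, tested code, not a fixture.

# The severity response

A bar-drop survey scores 150-200 colonies per reef into four categories:
normal, pale, partially bleached, fully bleached. With counts $c_2, c_3, c_4$
in the three affected categories out of $n$ colonies, the bleaching severity
index is

$$\mathrm{BSI} = 100\cdot\frac{(c_2 + 2c_3 + 3c_4)/3}{n}.$$

The weights grade ecological impact; the division by 3 normalizes to $[0,1]$
and the factor 100 puts the index on a percent-like scale: a reef with 28% of
colonies fully bleached (rest normal) scores exactly 28.0. `reefheat` reports
BSI on the 0-100 scale everywhere; species-level severities (`bsi_sp`) stay
on $[0,1]$ because they act as weights inside the sensitivity index.

# Thermal metrics

All metrics derive from a validated per-site daily series (`sst_series`),
which enforces strictly daily, gap-free dates (gaps of up to 3 days are
linearly interpolated with a warning; longer gaps abort ingest) and a
plausible temperature range. Seventeen metrics are computed at a sampling
date (`exposure_metrics()`):

* **MMM** — the climatological mean of the hottest calendar month, from plain
  monthly means pooled over the baseline (default 1985-2012). No
  satellite-era re-centering is applied; the baseline definition is the
  classical one.
* **Hotspots** — $\mathrm{HS}(t) = \max(\mathrm{SST}(t) - \mathrm{MMM}, 0)$.
* **Degree Heating Weeks** — $\tfrac17\sum \mathrm{HS}_i$ over a trailing
  window, counting only days with $\mathrm{HS}_i \ge 1$ °C (inclusive).
  Windows of 28, 84 (the conventional product) and 555 days capture
  short-term, seasonal and chronic accumulation. Windows are trailing and
  include the sampling date, so same-day acute stress is captured.
* **HS sums, means and exceedance counts** — accumulated hotspots over
  28/84/555 days (no threshold), the 3-day mean hotspot, and counts of days
  above 1 or 2 °C in 28/84-day windows.
* **Seasonal warming rate (ROTC)** — weekly means over consecutive 7-day
  blocks anchored at 1 January (partial trailing block dropped); the year's
  maximum weekly mean is located and the least-squares slope over the 12
  weeks ending at the maximum is the annual rate. Its average over the
  baseline years is the climatological rate. A flat series has rate zero by
  convention. The recent-rate metric scans all 84 candidate end-days before
  sampling and reports the maximum trailing 12-week slope, reading "maximum
  rate observed in the last three months" as a scan rather than a single
  window.
* **Trend of annual maximum DHW** — per year, the maximum daily 84-day DHW;
  the linear trend across years is fitted by iterated feasible generalized
  least squares with AR(1) errors (Cochrane-Orcutt), falling back to
  ordinary least squares when the autocorrelation estimate is degenerate
  (|rho| > 0.98). Negative trends are allowed.
* **Delta-DHW** — the year-to-date maximum daily DHW minus the previous
  calendar year's maximum. The sign convention is positive when the current
  event is hotter, so high values mean high stress relative to recent
  experience. Calendar years operationalize "current event" and "last year";
  a trailing-365-day reading would differ only for events spanning New Year,
  which the survey season (October-November) avoids.

Invariants checked in the test suite: DHW equals a brute-force loop oracle to
machine precision; the 28/84/555-day windows nest; all hotspot-family metrics
are monotone in any single day's temperature and invariant to joint
translation of series and MMM; a linear ramp of $m$ °C/day gives a rate of
exactly $7m$ °C/week.

# Reef sensitivity metrics

* **Species severity table** (`species_bsi_table`) — colonies pooled across
  all surveys per species, severity index on $[0,1]$. Species with fewer
  than `min_colonies` (default 50) pooled colonies are excluded: severity
  estimates from a handful of colonies are dominated by sampling noise.
* **SI_reef** — the abundance-weighted mean of species severities,
  $\sum_i (N_i/100)\, \mathrm{bsi}_{sp,i}$ with abundances in percent of
  classifiable colonies. Colonies of species without a table entry leave both
  numerator and denominator. The index is a convex combination of the
  contributing species severities.
* **RFI** — the same weighted mean over species functional coefficients
  (morphology/growth proxies). Missing coefficients fall back to a congener
  (same genus); colonies with no assignable value are dropped.
* **Richness and Hill N1** — species count and the exponential of Shannon
  entropy ("effective species"), computed through `vegan`.
* **DCA axis 1** (`dca_axis1`) — detrended correspondence analysis (via
  `vegan::decorana`) on the observation-by-species relative-abundance
  matrix; 26 detrending segments, no nonlinear axis rescaling (rescaling is
  an additional transformation the analysis does not need and whose use is a
  judgment call; disabling it keeps the axis interpretable and testable
  against a plain correspondence-analysis oracle). The axis sign is
  algebraically arbitrary; scores are oriented to correlate positively with
  the relative abundance of the overall most abundant species, a
  deterministic convention that makes reruns reproducible.

Deriving the sensitivity table from the same surveys it scores is circular;
that circularity is inherent to event-derived sensitivity indices. The
pipeline makes it explicit: `indices_table()` accepts an external table, and
a `leave_one_site_out` mode recomputes the table without the focal site for
honest evaluation.

# Robust statistics

* **Yuen's paired test** (`yuen_paired`) — the trimmed mean of the paired
  differences tested against zero with the winsorized variance of the
  differences, $h-1$ degrees of freedom ($h$ = observations left after
  trimming), default 10% trim per tail. At zero trim it is exactly the
  classical paired t-test, which the tests verify to $10^{-8}$. The effect
  size is a robust standardized measure: the trimmed mean over the
  winsorized SD rescaled by the normal-consistency constant (0.642 at 20%
  trim, 1 at zero trim).
* **Collinearity screen** — greedy in order of model influence: keep a
  predictor iff $|r| < 0.6$ against everything already kept, so the more
  informative member of a correlated pair survives. **VIF screen** —
  iteratively drop the largest variance inflation factor until all are
  below 4. The correlation screen runs before the VIF screen.
* **Friedman-Popescu H** (`friedman_h`) — for a predictor pair, the square
  root of the share of (centered) joint partial-dependence variance not
  explained by the sum of the one-dimensional partial dependences, evaluated
  at up to 100 observed predictor combinations. Zero for additive surfaces.
* **Partial dependence with bootstrap bands** (`partial_dependence_ci`) —
  case-resampling bootstrap: refit on resampled rows, re-evaluate the curve
  on a fixed grid, take pointwise 2.5/97.5 percentiles. Case resampling is
  used because the quantity of interest is the fitted surface itself, not a
  residual distribution.
* **Spline correlogram** (`spline_correlogram`) — Moran-type pairwise
  similarities of the standardized variable smoothed against great-circle
  distance (haversine, km) with a cubic smoothing spline; pointwise 95%
  envelope by bootstrapping sites. The spline's equivalent degrees of
  freedom are fixed at $\sqrt{n_\text{sites}}$ (the conventional
  correlogram choice): automatic smoothing selection by cross-validation is
  unstable on the tied pair distances a site bootstrap produces and can
  oscillate between near-interpolation and over-smoothing. The distance grid
  stops at the 75th percentile of pairwise distances because the tail is
  data-sparse.

# The driver model

The boosted-tree analysis (`fit_gbm`, `simplify_model`) is backed by
`xgboost` with squared-error loss, 0.5 row subsampling per tree and 10-fold
cross-validation. The hyperparameter protocol follows boosted-regression-tree
practice:

1. Tree complexity (depth 3, 4, 5) is compared at the fastest learning rate
   (0.01) by CV deviance.
2. The learning rate is lowered along the ladder 0.01, 0.005, 0.0025, 0.001
   at the chosen complexity until the CV-optimal ensemble sustains at least
   1000 trees — the standard guard against a learning rate too fast for the
   data. If no rate qualifies (e.g. signal-free data, where no amount of
   shrinkage produces 1000 useful trees), the best available point is used
   with a warning rather than an error, so null analyses still return their
   (near-zero) cross-validated fit.
3. `cv_r2` is the cross-validated fraction of variance explained,
   $1 - \mathrm{CV\,MSE}/\mathrm{null\,MSE}$.

Model simplification: fit the global model on all candidate metrics, rank by
relative influence (split-gain importance normalized to 100), apply the
correlation screen in influence order, then the VIF screen, then iteratively
remove low-influence predictors while removal costs at most 0.005 of
`cv_r2`. Candidate removals are tested in batches of the least influential
predictors, halving the batch on rejection, so the number of refits grows
logarithmically; a whole batch must clear the same tolerance as a single
drop, which can only keep more predictors than one-at-a-time removal, never
fewer drivers. Batch refits run at the faster of the selected rate and 0.005
(they only compare candidate sets); the final model is refit at the selected
protocol point. Reported diagnostics: relative influence, partial-dependence
curves, the pairwise H matrix, residuals, and what each screen removed.

# The synthetic study generator

`gen_dataset()` emulates a three-year regional bleaching study:

* **Sites** — ~90 reefs along a ~1000 km coastline arc with log-uniform
  (1-100 km) spacing, depths uniform on 1.0-26.45 m.
* **SST** — daily from 1985: a seasonal sinusoid peaking in mid-September,
  a warming trend of 0.05-0.15 °C/decade, AR(1) daily anomalies
  (rho 0.8, marginal SD 0.3 °C, the persistence scale of satellite SST), and
  injected half-sine heat events. Survey years get one event each, with peak
  anomalies escalating over 2015-2017; historical years from 1995 carry
  occasional mild events so the long-term DHW trend varies across sites.
  Amplitude and mean are drawn so that site climatologies land in
  western-Caribbean ranges (MMM ≈ 28.6-29.1 °C, seasonal warming rate
  ≈ 0.19-0.25 °C/week); the test suite checks that at least 90% of sites
  fall inside those bands, and the event intensities keep 84-day DHW at
  sampling dates within ~0.5-13.7 °C-weeks.
* **Communities** — 5-34 species per site drawn from a 40-species Caribbean
  pool with symmetric-Dirichlet relative abundances (concentration 1.5,
  giving realistic dominance structure).
* **Surveys** — each colony's category is Binomial(3, s): with severity
  scores 0-3, this law makes the expected per-colony score equal the latent
  severity $s$ exactly, so the expected survey BSI is the abundance-weighted
  mean of species severities with no distributional correction. The latent
  severity combines the site's driver signal (a logistic function of
  z-scored true drivers), species sensitivity offsets (centered on the
  community mean so the composition effect enters only through the
  sensitivity driver coefficient), and site-level noise.
* **Calibration** — the latent noise SD is found by bisection at generation
  time so that the population R² of BSI on the true drivers matches the
  requested value (default 0.75) within ~0.02, with colony sampling noise
  accounted for analytically. A target of 0 instead zeroes the driver
  coefficients.

What the generator does **not** emulate: spatial correlation of SST between
sites (each site's anomalies are independent), oceanographic structure
(upwelling, currents, depth-dependent attenuation), species interactions,
colony size or partial mortality, and observer error. Passing tests
therefore demonstrate that the pipeline recovers known structure under
idealized sampling, not that it would do so under every field condition.

# Problem sizes and runtime choices

The validation suite exercises the full protocol at the scale of a regional
study: 87 sites × 3 years (261 observations), 22-23 candidate predictors,
20 generator seeds for the driver-recovery study, 2000 replicates for the
paired-test size check, and 300-replicate bootstrap envelopes. These sizes
were chosen to make each check statistically meaningful while keeping a full
run of the suite on a single core practical.

# Known limitations

* Gridded (NetCDF) SST input is not supported; the interchange format is a
  long CSV of per-site daily values. Extraction from gridded products is
  upstream of this package.
* The learning-rate ladder is a discretization of the conventional
  0.01-0.001 range; data demanding rates outside it will trigger the
  fallback warning.
* The correlogram's envelope is pointwise, not simultaneous; reading it
  across many distances overstates significance.
* Leave-one-site-out sensitivity tables recompute the species table per
  site, which is quadratic in sites and meant for evaluation, not routine
  runs.
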