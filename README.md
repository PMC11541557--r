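# reefheat

Coral bleaching vulnerability analysis from daily sea-surface temperature
(SST) records and colony-level bleaching surveys.

Regional bleaching studies ask two questions: *how severely did each reef
bleach*, and *which combination of heat stress exposure and intrinsic reef
sensitivity explains the spatial variation in severity*. `reefheat` is a
toolbox for ecologists running such analyses. It computes:

- **Thermal exposure metrics** from daily SST (17 per site and date):
  hotspots `HS(t) = max(SST(t) − MMM, 0)` above the maximum-monthly-mean
  climatology; Degree Heating Weeks `DHW = (1/7) Σ HS_i [HS_i ≥ 1 °C]` over
  28/84/555-day trailing windows; hotspot sums, means and exceedance-day
  counts; the climatological seasonal warming rate (the 12-week pre-peak
  slope of weekly mean SST, averaged over 1985–2012) and its recent maximum;
  recent SST variability; the AR(1)-GLS trend of annual maximum DHW; and the
  change in maximum DHW relative to the previous year (ΔDHW).
- **Reef sensitivity metrics** from bar-drop surveys: the bleaching severity
  index `BSI = 100 · ((c₂ + 2c₃ + 3c₄)/3)/n` over pale/partially/fully
  bleached colony counts; species-level severities; the abundance-weighted
  reef sensitivity index `SI_reef = Σ (Ncc_i/100) · BSIsp_i`; the reef
  functional index; richness; Hill N1 diversity `exp(−Σ p_i ln p_i)`; and a
  detrended-correspondence-analysis ordination score.
- **Driver identification** with gradient-boosted regression trees
  (squared-error loss, bag fraction 0.5, 10-fold CV, ≥1000 trees at the
  selected learning rate), including collinearity (|r| < 0.6) and VIF (< 4)
  screening, stepwise simplification, relative influence,
  partial-dependence curves with bootstrap confidence bands, Friedman's
  H interaction statistic, and a spline correlogram of model residuals for
  spatial autocorrelation.
- **Robust inference**: Yuen's paired trimmed-means test with a robust
  effect size for year-over-year severity comparisons.
- **A synthetic study generator** with known driver structure and calibrated
  generative R², so the whole pipeline can be validated end to end without
  restricted field data.

## Worked example

```r
library(reefheat)

# a synthetic 30-site, 3-year study with known drivers
ds <- gen_dataset(n_sites = 30, years = 2015:2017, seed = 7)

cl <- climatology(ds$sst[["site_004"]])
#> <climatology> site site_004 (1985-2012): MMM 28.691 degC, ROTC_clim 0.2234 degC/week

em <- exposure_metrics(ds$sst[["site_004"]], cl, as.Date("2017-10-20"))
round(unlist(em[c("dhw", "hs_28days", "delta_dhw", "trend_dhw")]), 3)
#>       dhw hs_28days delta_dhw trend_dhw
#>     8.702    44.130    -0.762     1.264
```

The site accumulated 8.7 °C-weeks of heat stress in the 84 days before the
survey and 44.1 °C of summed hotspot anomalies in the last 28 days — a
severe event — while its ΔDHW of −0.8 °C-weeks says the previous year was
comparably hot.

```r
ix <- indices_table(ds$surveys)
head(ix[c("site_id", "date", "bsi", "si_reef", "richness", "diversity_n1")], 3)
#>    site_id       date   bsi si_reef richness diversity_n1
#> 1 site_004 2015-10-03 45.96   0.350       27         20.2
#> 2 site_018 2015-10-03 29.04   0.285       20         15.4
#> 3 site_013 2015-10-04  2.29   0.290       19         15.9
```

`bsi` is the 0–100 severity of each observation; `si_reef` the expected
community sensitivity (abundance-weighted species severities). Year-over-year
comparison at re-sampled sites:

```r
yr <- as.integer(format(as.Date(ix$date), "%Y"))
p <- paired_sample(ix$site_id[yr == 2017], ix$bsi[yr == 2017],
                   ix$site_id[yr == 2016], ix$bsi[yr == 2016])
yuen_paired(p$x, p$y)
#> Yuen paired trimmed-means test (trim = 0.10, n = 30)
#>   t = 2.1117, df = 23, p = 0.04578
#>   trimmed mean difference = 10.0038, robust effect size = 0.399
```

2017 bleached about 10 BSI points more severely than 2016 at the same reefs.
Driver identification on the full-scale study (87 sites, 261 observations,
true drivers `rotc_clim` −, `hs_28days` +, `si_reef` +, generative
R² = 0.75):

```r
ds <- gen_dataset(n_sites = 87, seed = 1)
ix <- indices_table(ds$surveys)
tab <- merge_model_table(ds$metrics, ix)
fit <- simplify_model(tab[model_predictor_names(tab)], tab$bsi,
                      model_config(seed = 1))
fit
#> <driver_model_result> CV R2 = 0.716 (global 0.667), 2007 trees
#> Relative influence (%):
#>   si_reef         38.44
#>   hs_28days       32.53
#>   rotc_clim       21.79
#>   hs_84days        7.25
#> Max pairwise interaction H = 0.156
```

The simplified model keeps the three generating drivers (plus one residual
heat metric), explains a cross-validated share of variance close to the
generative 0.75, and finds only weak pairwise interactions (all H well
below 0.25), consistent with the additive driver structure the data were
generated with.

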