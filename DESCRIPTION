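Package: reefheat
Title: Coral Bleaching Vulnerability from Heat-Stress Metrics and Reef Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess coral reef vulnerability to bleaching from daily
    sea-surface-temperature records and colony-level bleaching surveys. Computes
    satellite-style heat stress and thermal variability metrics (hotspots,
    Degree Heating Weeks over several windows, maximum monthly mean climatology,
    climatological seasonal warming rates, heat-stress trends), field-based reef
    sensitivity indices (bleaching severity, species sensitivity, functional and
    diversity indices, compositional ordination scores), and identifies drivers
    of bleaching severity with gradient-boosted regression trees including
    collinearity screening, model simplification, partial dependence with
    bootstrap intervals, interaction statistics, and spline-correlogram checks
    for spatial autocorrelation of residuals. Includes a synthetic data
    generator with known driver structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    xgboost,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
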