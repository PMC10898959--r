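Package: masldlink
Title: Non-Linear Exposure-Response Link Functions for Air Pollution and
    Steatotic Liver Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and fitting non-linear exposure-response
    relationships ("link functions") between long-term ambient air-pollutant
    exposure and the odds of metabolic dysfunction-associated steatotic liver
    disease (MASLD) in health-checkup cohorts.  Implements a stepwise
    identification procedure: a Box-Tidwell linearity gate, percentile-binned
    empirical-logit curves with segmented (broken-stick) non-linear least
    squares for inflection-point estimation, candidate logistic models using
    linear, threshold (hinge), two-segment interaction and restricted cubic
    spline encodings, and AIC-based selection with a parsimony rule.  Includes
    a joint six-pollutant logistic model with segment-wise adjusted odds
    ratios, collinearity diagnostics and adjusted predicted curves, cohort
    construction utilities (MASLD classification, exclusion cascade,
    trailing-window exposure averaging, covariate encoding), and a synthetic
    cohort generator with configurable true dose-response shapes for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
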