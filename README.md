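# masldlink

Tools for discovering and fitting **non-linear exposure–response "link
functions"** between long-term ambient air-pollutant exposure and the odds of
**metabolic dysfunction-associated steatotic liver disease (MASLD)** in
health-checkup cohorts — together with a synthetic-cohort generator so that
every stage of the pipeline can be validated against known ground truth.

## Who this is for

Epidemiologists and biostatisticians modelling dose–response relationships
between routinely monitored pollutants (PM2.5, PM10, O3, CO, SO2, NO2) and a
binary clinical outcome, when proportional (log-linear) odds cannot be taken
for granted.

## The method

For each pollutant `x` entering a logistic model for MASLD, the package
implements a stepwise identification of the encoding `f(x)` in

```
logit P(MASLD) = alpha + f(x) + gamma' z
```

where `z` are adjustment covariates (age, sex, marriage, education, income,
alcohol, smoking, diet, exercise, enrollment year; diabetes, hypertension and
dyslipidemia are left unadjusted because they are part of the outcome
definition):

1. **Box–Tidwell gate** — a logistic fit with `{x, x·ln x}`; a
   non-significant `x·ln x` term (α = 0.05) retains the *linear* link.
2. **Empirical-logit curve** — exposure is split into 100 percentile bins;
   each bin contributes `ln((cases + ½)/(non-cases + ½))`.
3. **Segmented NLLS** — the inflection point `c` is estimated by minimizing
   the bin-size-weighted SSE of the continuous broken-stick
   `a + b₁x + (b₂−b₁)(x−c)₊` (profile grid search plus local refinement).
4. **Candidate links** — *linear*; *threshold* (hinge `(x−c)₊`, flat
   baseline below `c`); *interaction* (`x`, `1{x≥c}`, `x·1{x≥c}`: two slopes
   plus a level shift); *restricted cubic spline* (Harrell basis, default
   4 knots at conventional quantiles).
5. **AIC with parsimony** — adjusted-model AICs are compared; candidates
   within 10 of the minimum are "equally fitted" and the simplest wins
   (linear < threshold < interaction < RCS(3) < … < RCS(7)). If an RCS wins,
   splines with 3–7 knots are re-compared under the same rule.

The selected links feed a **joint six-pollutant logistic model** with
segment-wise adjusted odds ratios (threshold baselines are structurally
aOR = 1; RCS segments report the exposure-weighted average derivative with a
delta-method CI), categorized / all-linear / leave-one-out sensitivity
variants, tolerance–VIF collinearity diagnostics, and adjusted predicted
curves with co-pollutants and covariates held at their means.

Cohort construction utilities cover the MASLD classifier (sonographic
steatosis + ≥1 of 5 cardiometabolic criteria), the excess-alcohol rule, the
sequential exclusion cascade, trailing 1–4-year exposure-window averaging
with a 90% coverage rule, and Table-1-style descriptive summaries.

## Worked example

```r
library(masldlink)

cfg  <- sim_config(n_participants = 50000, seed = 1)   # study-like conditions
gen  <- generate_cohort(cfg)
built <- apply_exclusions(gen$participants)
cohort <- built$cohort
covs <- encode_covariates(cohort)$matrix

sel <- select_link(cohort$pm25, cohort$masld, covs, pollutant = "pm25")
sel
#> <selection_result> pm25
#>   Box-Tidwell p = 1.05e-37
#>   inflection point = 33.36
#>   chosen: <link_spec> pm25: threshold (cutpoint 33.36)
```

The generator's default truth gives PM2.5 a hinge at 34.64 µg/m³ with slope
log(1.068) above it; on this cohort the pipeline rejects linearity, places
the inflection at 33.4 µg/m³ (within a fraction of the exposure IQR of the
truth) and selects the threshold link. Feeding all six selected links into
`fit_multipollutant()` and comparing against `fit_categorized()` and
`fit_all_linear()` with `compare_models()` reproduces the qualitative
finding that the best-link model fits better (AIC lower by ≈290 and ≈215 on
this cohort) than the categorized and all-linear alternatives, and
`segment_or()` recovers an aOR of ≈1.063 per µg/m³ above the PM2.5
inflection.

## Documentation

The methods vignette (`vignettes/link-functions.Rmd`) documents the model,
the tunable parameters and their defaults, what the synthetic generator does
and does not emulate, the numerical choices (tie-breaks, search windows,
continuity corrections) and known limitations.
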