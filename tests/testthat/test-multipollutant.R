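# a moderately sized cohort with the full set of default nonlinear truths,
# shared across the joint-model tests
mp_cohort <- local({
  cfg <- method_config(20000, default_true_links(), seed = 4242,
                       covariate_effects = default_covariate_effects())
  labelled_cohort(cfg)
})
mp_cov <- encode_covariates(mp_cohort, vars = small_covariate_vars)$matrix
mp_specs <- list(
  pm25 = link_spec("pm25", "threshold", cutpoint = 34.64),
  pm10 = link_spec("pm10", "interaction", cutpoint = 57.93),
  co = link_spec("co", "interaction", cutpoint = 643.6),
  o3 = link_spec("o3", "rcs", knots = default_knots(mp_cohort$o3, 3)),
  so2 = link_spec("so2", "linear"),
  no2 = link_spec("no2", "rcs", knots = default_knots(mp_cohort$no2, 4)))
mp_fit <- fit_multipollutant(mp_cohort, mp_specs, mp_cov)

test_that("the joint model satisfies the AIC identity and basic structure", {
  expect_equal(mp_fit$aic, 2 * mp_fit$n_params - 2 * mp_fit$loglik,
               tolerance = 1e-8)
  expect_equal(length(mp_fit$col_map), 6L)
  widths <- vapply(mp_specs, basis_width, 0L)
  got <- vapply(mp_fit$col_map, length, 0L)
  expect_equal(unname(got[names(widths)]), unname(widths))
  expect_true(isSymmetric(mp_fit$vcov, tol = 1e-10))
})

test_that("the all-linear variant equals the joint fit with linear specs", {
  lin_specs <- lapply(names(mp_specs), function(p) link_spec(p, "linear"))
  names(lin_specs) <- names(mp_specs)
  f1 <- fit_all_linear(mp_cohort, mp_cov)
  f2 <- fit_multipollutant(mp_cohort, lin_specs, mp_cov)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
  # per-unit aOR is exp(coefficient) by definition
  j <- f1$col_map[["pm25"]]
  s <- segment_or(f1, "pm25", -Inf, Inf)
  expect_equal(s$aor, exp(unname(f1$coef[j])), tolerance = 1e-12)
})

test_that("subset models drop exactly the excluded basis columns", {
  f5 <- fit_subset(mp_cohort, mp_specs, mp_cov, exclude = "pm10")
  expect_equal(mp_fit$n_params - f5$n_params, basis_width(mp_specs$pm10))
  expect_false("pm10" %in% names(f5$col_map))
  # excluding all but one reduces to the one-pollutant likelihood
  f1 <- fit_subset(mp_cohort, mp_specs, mp_cov,
                   exclude = setdiff(names(mp_specs), "pm25"))
  g1 <- fit_candidate(mp_cohort$pm25, mp_cohort$masld, mp_specs$pm25, mp_cov)
  expect_equal(f1$loglik, g1$loglik, tolerance = 1e-8)
})

test_that("segment odds ratios follow each link's structure", {
  # threshold below the cutpoint: structurally 1 with zero-width interval
  s <- segment_or(mp_fit, "pm25", -Inf, 34.64)
  expect_identical(c(s$aor, s$lo, s$hi), c(1, 1, 1))
  expect_true(s$structural)
  s_above <- segment_or(mp_fit, "pm25", 34.64, Inf)
  j <- mp_fit$col_map[["pm25"]]
  expect_equal(s_above$aor, exp(unname(mp_fit$coef[j])), tolerance = 1e-12)
  expect_true(s_above$lo < s_above$aor && s_above$aor < s_above$hi)

  # interaction: slopes below and above differ by the interaction term
  sb <- segment_or(mp_fit, "pm10", -Inf, 57.93)
  sa <- segment_or(mp_fit, "pm10", 57.93, Inf)
  jj <- mp_fit$col_map[["pm10"]]
  expect_equal(log(sb$aor), unname(mp_fit$coef[jj[1]]), tolerance = 1e-12)
  expect_equal(log(sa$aor), unname(mp_fit$coef[jj[1]] + mp_fit$coef[jj[3]]),
               tolerance = 1e-12)

  # RCS: average derivative equals a finite-difference + weighted-mean oracle
  kn <- mp_specs$no2$knots
  jn <- mp_fit$col_map[["no2"]]
  xs <- mp_fit$exposures[, "no2"]
  seg <- xs[xs >= 33 & xs < 48]
  h <- 1e-6
  fitted_logit <- function(x) drop(rcs_basis(x, kn) %*% mp_fit$coef[jn])
  num_deriv <- (fitted_logit(seg + h) - fitted_logit(seg - h)) / (2 * h)
  s_rcs <- segment_or(mp_fit, "no2", 33, 48)
  expect_equal(log(s_rcs$aor), mean(num_deriv), tolerance = 1e-6)
  # endpoint-contrast variant is available and differs in general
  s_ep <- segment_or(mp_fit, "no2", 33, 48, method = "endpoint")
  expect_true(is.finite(s_ep$aor))
  expect_error(segment_or(mp_fit, "no2", 500, 600), "support")
})

test_that("categorized models use the lowest segment as reference", {
  cuts <- list(pm25 = 34.64, no2 = c(33, 48))
  fc <- fit_categorized(mp_cohort, cuts, mp_cov)
  tab <- categorized_or(fc)
  ref <- tab[tab$segment %in% c("< 34.64", "< 33"), ]
  expect_true(all(ref$aor == 1))
  expect_equal(nrow(tab[tab$pollutant == "no2", ]), 3L)
  expect_true(all(tab$lo[!is.na(tab$lo)] <= tab$aor[!is.na(tab$lo)]))
  expect_error(fit_categorized(mp_cohort, list(pm25 = 1000), mp_cov),
               "empty exposure segment")
})

test_that("the best-link model outfits categorized and all-linear variants", {
  cuts <- list(pm25 = 34.64, pm10 = 57.93, co = 643.6,
               o3 = 56, so2 = 10, no2 = c(33, 48))
  fc <- fit_categorized(mp_cohort, cuts, mp_cov)
  fl <- fit_all_linear(mp_cohort, mp_cov)
  cmp <- compare_models(list(best_link = mp_fit, categorized = fc, all_linear = fl))
  expect_equal(cmp$model[1], "best_link")
  expect_equal(cmp$delta_aic[1], 0)
  # ordering invariant to input order
  cmp2 <- compare_models(list(all_linear = fl, best_link = mp_fit, categorized = fc))
  expect_equal(cmp$model, cmp2$model)
  expect_equal(cmp$aic, cmp2$aic)
})

test_that("AIC comparison refuses models from different cohorts", {
  other <- mp_cohort[1:10000, ]
  f_other <- fit_all_linear(other, mp_cov[1:10000, ])
  expect_error(compare_models(list(a = mp_fit, b = f_other)), "different cohorts")
})

test_that("collinearity diagnostics match direct auxiliary regressions", {
  # orthogonal columns: VIF exactly 1
  X <- cbind(a = rep(c(1, -1), 50), b = rep(c(1, 1, -1, -1), 25))
  d <- collinearity_diagnostics(X)
  expect_equal(d$terms$vif, c(1, 1), tolerance = 1e-12)
  # duplicated column: tolerance 0, infinite VIF
  Xd <- cbind(X, a2 = X[, "a"])
  dd <- collinearity_diagnostics(Xd)
  expect_true(all(is.infinite(dd$terms$vif[c(1, 3)])))
  expect_equal(dd$terms$tolerance[c(1, 3)], c(0, 0))
  # fixture matrix against explicit R^2 regressions
  set.seed(8)
  Z <- matrix(rnorm(300), 100, 3)
  Z <- cbind(Z, Z %*% c(1, 2, 3) + rnorm(100, sd = 0.5))
  colnames(Z) <- paste0("v", 1:4)
  dz <- collinearity_diagnostics(Z)
  for (j in 1:4) {
    r2 <- summary(lm(Z[, j] ~ Z[, -j]))$r.squared
    expect_equal(dz$terms$r_squared[j], r2, tolerance = 1e-10)
    expect_equal(dz$terms$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
  # Pearson correlations with Fisher-z limits bracketing the estimate
  expect_true(all(dz$correlations$lo < dz$correlations$r &
                    dz$correlations$r < dz$correlations$hi))
})

test_that("predicted curves reproduce the model's own predictions", {
  grid <- seq(quantile(mp_cohort$pm25, .02), quantile(mp_cohort$pm25, .98),
              length.out = 25)
  pc <- predicted_curve(mp_fit, "pm25", grid)
  # direct evaluation: basis at grid + all other columns at their means
  j <- mp_fit$col_map[["pm25"]]
  manual <- drop(basis_matrix(grid, mp_specs$pm25) %*% mp_fit$coef[j]) +
    sum(mp_fit$design_means[-j] * mp_fit$coef[-j])
  expect_equal(pc$logit, manual, tolerance = 1e-12)
  # threshold link: flat below the cutpoint, linear above
  below <- pc$logit[grid < 34.64]
  expect_lt(diff(range(below)), 1e-12)
  above <- grid > 34.64
  slopes <- diff(pc$logit[above]) / diff(grid[above])
  expect_equal(slopes, rep(unname(mp_fit$coef[j]), sum(above) - 1),
               tolerance = 1e-8)
  # linear pollutant: exact straight line with slope = coefficient
  grid_so2 <- seq(5, 20, length.out = 10)
  pcs <- predicted_curve(mp_fit, "so2", grid_so2)
  js <- mp_fit$col_map[["so2"]]
  expect_equal(diff(pcs$logit) / diff(grid_so2),
               rep(unname(mp_fit$coef[js]), 9), tolerance = 1e-10)
  expect_error(predicted_curve(mp_fit, "pm25", c(grid, 1e4)), "beyond")
})

test_that("null pollutant effects give segment aORs compatible with 1", {
  covered <- unlist(lapply(606:608, function(seed) {
    cfg <- method_config(20000, null_links(), seed = seed,
                         covariate_effects = default_covariate_effects())
    p <- labelled_cohort(cfg)
    cov <- encode_covariates(p, vars = small_covariate_vars)$matrix
    f <- fit_all_linear(p, cov)
    vapply(names(f$col_map), function(pol) {
      s <- segment_or(f, pol, -Inf, Inf)
      s$lo <= 1 && 1 <= s$hi
    }, TRUE)
  }))
  # 18 nominal-95% intervals across three null cohorts: nearly all cover 1
  expect_gte(sum(covered), 14L)
})
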