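# Synthetic health-checkup cohorts with correlated multi-pollutant exposure
# and a configurable true dose-response shape per pollutant, so every
# downstream stage of the pipeline can be exercised against known truth.

.pollutants <- c("pm25", "pm10", "co", "o3", "so2", "no2")

# Whole-cohort 3-year exposure moments (ug/m3), pooled across strata.
.default_means <- c(pm25 = 30.6, pm10 = 51.7, co = 704.0,
                    o3 = 52.8, so2 = 10.8, no2 = 37.5)
.default_sds <- c(pm25 = 6.6, pm10 = 13.0, co = 234.8,
                  o3 = 6.5, so2 = 4.0, no2 = 9.6)

#' Default inter-pollutant correlation matrix
#'
#' Pairwise Pearson correlations of the 3-year average exposures.  The
#' PM2.5-PM10 (0.770) and PM10-SO2 (0.677) entries follow reported
#' monitoring-network values; the remaining pairs are plausible values for
#' co-emitted urban pollutants, with ozone mildly anti-correlated with NO2
#' (titration chemistry).
#'
#' @return A 6x6 symmetric positive-definite correlation matrix.
#' @export
default_pollutant_corr <- function() {
  R <- diag(6)
  dimnames(R) <- list(.pollutants, .pollutants)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_r("pm25", "pm10", 0.770)
  set_r("pm25", "co", 0.45); set_r("pm25", "o3", 0.30)
  set_r("pm25", "so2", 0.60); set_r("pm25", "no2", 0.50)
  set_r("pm10", "co", 0.40); set_r("pm10", "o3", 0.30)
  set_r("pm10", "so2", 0.677); set_r("pm10", "no2", 0.50)
  set_r("co", "o3", -0.10); set_r("co", "so2", 0.30); set_r("co", "no2", 0.60)
  set_r("o3", "so2", 0.20); set_r("o3", "no2", -0.20)
  set_r("so2", "no2", 0.45)
  R
}

#' Create a true dose-response ("true link") specification
#'
#' Describes the contribution of one pollutant's 3-year average exposure to
#' the latent log-odds of the outcome in the generator.
#'
#' @param shape One of `"linear"`, `"hinge"`, `"piecewise_jump"`, `"spline"`.
#' @param cutpoint Inflection point in ug/m3 (`"hinge"`/`"piecewise_jump"`).
#' @param slope_below,slope_above Log-odds per ug/m3 below/above the
#'   cutpoint; for `"linear"`, `slope_below` is the single slope.
#' @param jump Log-odds discontinuity at the cutpoint (`"piecewise_jump"`).
#' @param knots,coefs Restricted-cubic-spline knots and the
#'   `length(knots) - 1` basis coefficients (`"spline"`).
#' @return An object of class `true_link`.
#' @export
true_link <- function(shape, cutpoint = NULL, slope_below = 0,
                      slope_above = 0, jump = 0, knots = NULL, coefs = NULL) {
  shape <- match.arg(shape, c("linear", "hinge", "piecewise_jump", "spline"))
  if (shape %in% c("hinge", "piecewise_jump") &&
      (is.null(cutpoint) || !is.finite(cutpoint))) {
    stop("shape '", shape, "' requires a finite cutpoint")
  }
  if (shape == "spline") {
    if (is.null(knots) || is.null(coefs)) stop("spline requires knots and coefs")
    if (length(coefs) != length(knots) - 1L) {
      stop("spline needs length(knots) - 1 coefficients")
    }
  }
  structure(list(shape = shape, cutpoint = cutpoint,
                 slope_below = slope_below, slope_above = slope_above,
                 jump = jump, knots = knots, coefs = coefs),
            class = "true_link")
}

#' Evaluate a true dose-response contribution
#'
#' @param link A [true_link()].
#' @param x Numeric exposure vector (ug/m3).
#' @return Numeric log-odds contribution, same length as `x`.
#' @export
eval_true_link <- function(link, x) {
  stopifnot(inherits(link, "true_link"))
  switch(link$shape,
    linear = link$slope_below * x,
    hinge = link$slope_below * x +
      (link$slope_above - link$slope_below) * pmax(0, x - link$cutpoint),
    piecewise_jump = link$slope_below * x + (x >= link$cutpoint) *
      (link$jump + (link$slope_above - link$slope_below) * (x - link$cutpoint)),
    spline = drop(rcs_basis(x, link$knots) %*% link$coefs))
}

#' Default true link shapes for the six pollutants
#'
#' One representative of each candidate family, at realistic inflection
#' points and effect sizes: a hinge for PM2.5 (flat below 34.64 ug/m3), a
#' discontinuous two-segment shape for PM10 (cut 57.93) and CO (cut 643.6),
#' restricted cubic splines for O3 (3 knots) and NO2 (4 knots), and a null
#' linear shape for SO2.
#'
#' @return Named list of [true_link()] objects.
#' @export
default_true_links <- function() {
  list(
    pm25 = true_link("hinge", cutpoint = 34.64,
                     slope_below = 0, slope_above = log(1.068)),
    pm10 = true_link("piecewise_jump", cutpoint = 57.93,
                     slope_below = log(0.992), slope_above = log(1.019),
                     jump = 0.10),
    co = true_link("piecewise_jump", cutpoint = 643.6,
                   slope_below = log(1.0006), slope_above = log(1.0001),
                   jump = 0.05),
    o3 = true_link("spline", knots = c(44.5, 52.8, 61.1),
                   coefs = c(-0.004, 0.0067)),
    so2 = true_link("linear", slope_below = 0),
    no2 = true_link("spline", knots = c(21.7, 33.8, 41.2, 53.3),
                    coefs = c(-0.008, 0.0262, -0.0896))
  )
}

#' Default covariate effects on the latent log-odds
#'
#' Log-odds contributions of the questionnaire covariates.  Age acts per
#' year, centered at the cohort mean; categorical effects are relative to
#' the reference level (zero).
#'
#' @return Named list: numeric scalars for continuous covariates, named
#'   numeric vectors (per non-reference level) for categorical ones.
#' @export
default_covariate_effects <- function() {
  list(age = 0.045,
       sex = c(male = 1.20),
       marriage = c(married = 0.15),
       smoking = c(former = 0.25, current = 0.30),
       alcohol_status = c(former = 0.20, current = 0.15),
       fried_intake = c(moderate = 0.05, frequent = 0.12))
}

#' Default per-rule exclusion probabilities
#'
#' Marginal probabilities used by the generator to seed records triggering
#' each exclusion rule, at rates similar to a large checkup cohort.
#' `cryptogenic_sld` applies among steatotic participants; `age_under_18`
#' arises from the age distribution rather than a separate flag.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_exclusion_fractions <- function() {
  c(missing_exposure_or_sono = 0.046, missing_masld_fields = 0.092,
    missing_alcohol = 0.062, cirrhosis_or_hcc = 0.0014, hepatitis = 0.114,
    excess_alcohol = 0.019, sono_abnormality = 0.0074,
    cryptogenic_sld = 0.058)
}

#' Simulation configuration for the synthetic cohort generator
#'
#' @param n_participants Number of participants (default 20000).
#' @param pollutant_means,pollutant_sds Named per-pollutant 3-year exposure
#'   moments in ug/m3 (CO in ug/m3 as conventionally reported).
#' @param pollutant_corr 6x6 correlation matrix (symmetric PSD, unit
#'   diagonal).
#' @param true_links Named list of [true_link()] objects, one per pollutant.
#' @param covariate_effects See [default_covariate_effects()]; pass an empty
#'   list for no covariate effects.
#' @param intercept Fixed latent-logit intercept, or `NULL` (default) to
#'   calibrate it so the analyzed-cohort MASLD prevalence matches
#'   `prevalence_target`.
#' @param prevalence_target Target MASLD prevalence in the analyzed cohort
#'   (default 0.406).
#' @param cryptogenic_frac Fraction of steatotic participants generated with
#'   zero cardiometabolic criteria (default 0.058).
#' @param exclusion_fractions See [default_exclusion_fractions()]; pass 0s
#'   for an exclusion-free cohort.
#' @param ar1_rho Month-to-month AR(1) correlation of monthly exposure
#'   deviations (default 0.9).
#' @param between_share Fraction of 3-year-mean exposure variance carried by
#'   the stable between-participant component (default 0.8).
#' @param months_of_exposure Monthly history length per participant
#'   (default 48, i.e. enough for 1- to 4-year windows).
#' @param seed Integer random seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20000L,
                       pollutant_means = .default_means,
                       pollutant_sds = .default_sds,
                       pollutant_corr = default_pollutant_corr(),
                       true_links = default_true_links(),
                       covariate_effects = default_covariate_effects(),
                       intercept = NULL,
                       prevalence_target = 0.406,
                       cryptogenic_frac = 0.058,
                       exclusion_fractions = default_exclusion_fractions(),
                       ar1_rho = 0.9,
                       between_share = 0.8,
                       months_of_exposure = 48L,
                       seed = 1L) {
  stopifnot(n_participants >= 1,
            prevalence_target > 0, prevalence_target < 1,
            all(pollutant_sds > 0),
            months_of_exposure >= 48L,
            ar1_rho >= 0, ar1_rho < 1,
            between_share >= 0, between_share <= 1)
  R <- as.matrix(pollutant_corr)
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8)) {
    stop("pollutant_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("pollutant_corr is not positive semi-definite")
  stopifnot(setequal(names(pollutant_means), .pollutants),
            setequal(names(pollutant_sds), .pollutants),
            setequal(names(true_links), .pollutants))
  structure(list(
    n_participants = as.integer(n_participants),
    pollutant_means = pollutant_means[.pollutants],
    pollutant_sds = pollutant_sds[.pollutants],
    pollutant_corr = R[.pollutants, .pollutants],
    true_links = true_links[.pollutants],
    covariate_effects = covariate_effects,
    intercept = intercept,
    prevalence_target = prevalence_target,
    cryptogenic_frac = cryptogenic_frac,
    exclusion_fractions = exclusion_fractions,
    ar1_rho = ar1_rho,
    between_share = between_share,
    months_of_exposure = as.integer(months_of_exposure),
    seed = as.integer(seed)), class = "sim_config")
}

.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

.sample_level <- function(n, levels, probs) {
  levels[1L + findInterval(stats::runif(n), cumsum(probs) / sum(probs))]
}

# variance of the mean of `m` consecutive values of a unit-variance AR(1)
.ar1_mean_var <- function(rho, m) {
  if (rho == 0) return(1 / m)
  l <- seq_len(m - 1L)
  (m + 2 * sum((m - l) * rho^l)) / m^2
}

# draw questionnaire covariates at pooled checkup-cohort frequencies;
# "unreported" socio-economic answers are stored as NA
.draw_covariates <- function(n) {
  marriage <- .sample_level(n, c("single", "married", NA), c(.371, .578, .051))
  education <- .sample_level(n, c("illiterate", "elementary_middle",
                                  "high_school", "college_plus", NA),
                             c(.011, .086, .343, .543, .017))
  income <- .sample_level(n, c("lt_28k", "usd_28k_70k", "ge_70k", NA),
                          c(.405, .397, .073, .124))
  data.frame(
    age = round(.rtruncnorm(n, 40.5, 12.3, 15, 90), 1),
    sex = .sample_level(n, c("female", "male"), c(.520, .480)),
    marriage = marriage, education = education, income = income,
    smoking = .sample_level(n, c("never", "former", "current"), c(.773, .064, .163)),
    alcohol_status = .sample_level(n, c("never", "former", "current"), c(.853, .022, .125)),
    veg_intake = .sample_level(n, c("seldom", "moderate", "frequent"), c(.172, .601, .226)),
    fruit_intake = .sample_level(n, c("seldom", "moderate", "frequent"), c(.324, .550, .126)),
    sugary_intake = .sample_level(n, c("seldom", "moderate", "frequent"), c(.353, .482, .165)),
    fried_intake = .sample_level(n, c("seldom", "moderate", "frequent"), c(.293, .529, .178)),
    regular_exercise = stats::runif(n) < .328,
    stringsAsFactors = FALSE)
}

.covariate_eta <- function(cov_df, effects, age_center = 40.5) {
  eta <- numeric(nrow(cov_df))
  for (v in names(effects)) {
    eff <- effects[[v]]
    col <- cov_df[[v]]
    if (is.null(col)) next
    if (is.numeric(col) && length(eff) == 1L && is.null(names(eff))) {
      center <- if (v == "age") age_center else mean(col, na.rm = TRUE)
      eta <- eta + eff * (col - center)
    } else {
      idx <- match(as.character(col), names(eff))
      add <- ifelse(is.na(idx), 0, eff[idx])
      eta <- eta + add
    }
  }
  eta
}

# clinical fields conditional on intended steatosis status, at the stratified
# moments of a checkup cohort
.draw_clinical <- function(n, steat, male) {
  pick <- function(m1, s1, m0, s0) ifelse(steat, stats::rnorm(n, m1, s1),
                                          stats::rnorm(n, m0, s0))
  bmi <- pmax(pick(26.2, 3.4, 21.3, 2.6), 14)
  wc <- pmax(ifelse(male, pick(88.0, 8.0, 77.7, 6.9),
                    pick(79.7, 8.1, 68.2, 5.9)), 50)
  glucose <- pmax(pick(102, 20, 92, 10), 55)
  hba1c <- pmax(pick(5.8, 0.7, 5.4, 0.4), 3.8)
  sbp <- pmax(pick(123.5, 16.9, 111.0, 15.4), 75)
  dbp <- pmax(pick(77.1, 11.2, 69.5, 10.1), 40)
  tg <- pmax(pick(148.9, 94.4, 80.7, 44.2), 25)
  hdl <- pmax(ifelse(male, pick(49.2, 9.7, 57.1, 12.4),
                     pick(57.3, 12.6, 68.3, 14.7)), 15)
  ldl <- pmax(pick(124.1, 32.5, 106.8, 29.4), 30)
  chol <- pmax(pick(202.5, 36.1, 187.0, 32.8), 90)
  alt <- pmax(pick(37.5, 28.6, 19.7, 13.5), 4)
  data.frame(
    bmi = bmi, wc = wc, glucose = glucose, hba1c = hba1c, sbp = sbp,
    dbp = dbp, tg = tg, hdl = hdl, ldl = ldl, chol = chol, alt = alt,
    antihtn_tx = stats::runif(n) < ifelse(steat, 0.10, 0.03),
    lipid_tx = stats::runif(n) < ifelse(steat, 0.06, 0.02),
    antidm_tx = stats::runif(n) < ifelse(steat, 0.05, 0.01),
    diabetes_hx = stats::runif(n) < ifelse(steat, 0.099, 0.014))
}

# force every cardiometabolic criterion false (cryptogenic construction)
.force_no_criteria <- function(df, male) {
  i <- seq_len(nrow(df))
  df$bmi <- stats::runif(length(i), 19, 22.9)
  df$wc <- ifelse(male, stats::runif(length(i), 70, 93),
                  stats::runif(length(i), 60, 79))
  df$glucose <- stats::runif(length(i), 80, 99)
  df$hba1c <- stats::runif(length(i), 4.8, 5.6)
  df$sbp <- stats::runif(length(i), 100, 128)
  df$dbp <- stats::runif(length(i), 60, 83)
  df$tg <- stats::runif(length(i), 50, 148)
  df$hdl <- ifelse(male, stats::runif(length(i), 41, 60),
                   stats::runif(length(i), 51, 70))
  df$antihtn_tx <- FALSE; df$lipid_tx <- FALSE
  df$antidm_tx <- FALSE; df$diabetes_hx <- FALSE
  df
}

#' Generate a synthetic health-checkup cohort
#'
#' Draws `n_participants` with correlated 3-year average exposures for the
#' six pollutants (Gaussian copula, truncated at zero), questionnaire
#' covariates, cardiometabolic fields and a sonographic steatosis flag
#' driven by a latent logit
#' `intercept + sum_j f_j(exposure_j) + covariate effects`, where each `f_j`
#' is the pollutant's [true_link()].  When `intercept` is `NULL` it is
#' calibrated by bisection so that the MASLD prevalence among participants
#' surviving the exclusion cascade matches `prevalence_target`.
#' Cardiometabolic fields are generated so that the downstream MASLD
#' classifier reproduces the latent outcome: steatotic participants carry at
#' least one criterion unless deliberately generated cryptogenic.
#'
#' @param config A [sim_config()].
#' @param monthly If `TRUE`, also emit a long-format monthly exposure table
#'   (participant, pollutant, `"YYYY-MM"`, value) generated from a stable
#'   between-participant component plus an AR(1) monthly component, scaled
#'   so trailing 3-year means keep the configured moments and correlations.
#'   Default `FALSE` (the 3-year means are then drawn directly from the
#'   equivalent marginal distribution, which is much faster).
#' @return List with `participants` (data frame; includes per-pollutant
#'   3-year mean columns and all fields the exclusion cascade needs),
#'   `exposure` (long monthly table or `NULL`), and `truth` (list recording
#'   the seed, intercept, true links and covariate effects).
#' @export
generate_cohort <- function(config, monthly = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  mu <- config$pollutant_means; sdv <- config$pollutant_sds
  L <- t(chol(config$pollutant_corr + diag(1e-10, 6)))

  cov_df <- .draw_covariates(n)
  checkup_date <- as.Date("2010-01-01") +
    floor(stats::runif(n, 0, as.numeric(as.Date("2017-12-31") - as.Date("2010-01-01")) + 1))

  exposure_long <- NULL
  if (monthly) {
    w <- config$between_share
    rho <- config$ar1_rho
    kappa <- .ar1_mean_var(rho, 36L)
    M <- config$months_of_exposure
    B <- matrix(stats::rnorm(n * 6L), n, 6L) %*% t(L)
    E <- array(0, dim = c(n, 6L, M))
    E[, , 1L] <- matrix(stats::rnorm(n * 6L), n, 6L) %*% t(L)
    innov_sd <- sqrt(1 - rho^2)
    for (m in 2:M) {
      E[, , m] <- rho * E[, , m - 1L] +
        innov_sd * (matrix(stats::rnorm(n * 6L), n, 6L) %*% t(L))
    }
    idx0 <- .month_index(checkup_date)
    month_lab <- function(mi) sprintf("%04d-%02d", mi %/% 12L, mi %% 12L + 1L)
    Xmon <- array(0, dim = c(n, 6L, M))
    for (j in 1:6) {
      Xmon[, j, ] <- pmax(mu[j] + sdv[j] *
        (sqrt(w) * B[, j] + sqrt(1 - w) * E[, j, ] / sqrt(kappa)), 0)
    }
    # trailing 3-year mean from the last 36 of the M months before index
    X3 <- sapply(1:6, function(j) rowMeans(Xmon[, j, (M - 35L):M, drop = FALSE]))
    colnames(X3) <- .pollutants
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      mis <- (idx0[i] - M):(idx0[i] - 1L)
      rows[[i]] <- data.frame(
        participant_id = i,
        pollutant = rep(.pollutants, each = M),
        month = rep(month_lab(mis), times = 6L),
        value = as.vector(t(Xmon[i, , ])))
    }
    exposure_long <- do.call(rbind, rows)
  } else {
    Z <- matrix(stats::rnorm(n * 6L), n, 6L) %*% t(L)
    X3 <- pmax(sweep(sweep(Z, 2L, sdv, "*"), 2L, mu, "+"), 0)
    colnames(X3) <- .pollutants
  }

  eta0 <- .covariate_eta(cov_df, config$covariate_effects)
  for (j in .pollutants) {
    lk <- config$true_links[[j]]
    eta0 <- eta0 + eval_true_link(lk, X3[, j]) -
      eval_true_link(lk, mu[[j]])  # center so the intercept is interpretable
  }

  ef <- config$exclusion_fractions
  frac <- function(nm) if (nm %in% names(ef)) ef[[nm]] else 0
  miss_expo <- stats::runif(n) < frac("missing_exposure_or_sono")
  miss_masld <- stats::runif(n) < frac("missing_masld_fields")
  miss_alc <- stats::runif(n) < frac("missing_alcohol")
  cirr <- stats::runif(n) < frac("cirrhosis_or_hcc")
  hep <- stats::runif(n) < frac("hepatitis")
  sono_abn <- stats::runif(n) < frac("sono_abnormality")
  excess_target <- stats::runif(n) < frac("excess_alcohol")

  # rules that remove a record regardless of its outcome; the missing-MASLD
  # and cryptogenic rules only remove steatotic records and are handled
  # through the calibration factor A below
  eligible <- !(miss_expo | miss_alc | cirr | hep | sono_abn |
                  excess_target | cov_df$age < 18)

  cf <- config$cryptogenic_frac
  t0 <- config$prevalence_target
  # among the eligible, retained cases = p * A and retained non-cases =
  # 1 - p, where A discounts cryptogenic generation and missing-MASLD-field
  # exclusion (both bite steatotic records only); solve the analyzed
  # prevalence identity t = pA / (pA + 1 - p) for the steatosis rate p
  A <- (1 - cf) * (1 - frac("missing_masld_fields"))
  p_star <- t0 / (A * (1 - t0) + t0)
  if (is.null(config$intercept)) {
    f <- function(a) mean(stats::plogis(a + eta0[eligible])) - p_star
    if (f(-30) > 0 || f(30) < 0) stop("prevalence calibration unachievable")
    alpha <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  } else {
    alpha <- config$intercept
  }
  p <- stats::plogis(alpha + eta0)
  steat <- stats::runif(n) < p
  crypto <- steat & stats::runif(n) < cf

  male <- cov_df$sex == "male"
  clin <- .draw_clinical(n, steat, male)
  # intended MASLD cases must satisfy >= 1 criterion: bump BMI when none holds
  lab0 <- classify_masld(cbind(data.frame(steatosis_on_us = steat, sex = cov_df$sex), clin))
  need_bump <- steat & !crypto & lab0$category == "cryptogenic_sld"
  if (any(need_bump)) clin$bmi[need_bump] <- stats::runif(sum(need_bump), 23, 27)
  if (any(crypto)) clin[crypto, ] <- .force_no_criteria(clin[crypto, , drop = FALSE],
                                                        male[crypto])

  # alcohol quantity fields consistent with the excess-drinking rule
  drinks <- ifelse(cov_df$alcohol_status == "never", 0,
                   sample(0:1, n, replace = TRUE))
  days <- ifelse(cov_df$alcohol_status == "never", 0,
                 sample(0:7, n, replace = TRUE))
  yrs <- ifelse(cov_df$alcohol_status == "never", 0,
                round(stats::runif(n, 0, 30), 1))
  drinks[excess_target] <- round(stats::runif(sum(excess_target), 2, 6))
  days[excess_target] <- sample(3:7, sum(excess_target), replace = TRUE)
  yrs[excess_target] <- round(stats::runif(sum(excess_target), 2, 20), 1)

  participants <- data.frame(id = seq_len(n), checkup_date = checkup_date,
                             enrollment_year = as.integer(format(checkup_date, "%Y")),
                             cov_df,
                             alcohol_drinks_per_day = drinks,
                             alcohol_days_per_week = days,
                             alcohol_years = yrs,
                             clin,
                             cirrhosis_hx = cirr, hcc_hx = FALSE,
                             hepatitis_hx = hep,
                             steatosis_on_us = steat,
                             sig_sono_abnormality = sono_abn,
                             as.data.frame(X3),
                             exposure_missing = miss_expo,
                             stringsAsFactors = FALSE)
  # apply missingness masks after the latent logit has been computed
  participants$steatosis_on_us[miss_expo & stats::runif(n) < 0.5] <- NA
  participants[miss_expo, .pollutants] <- NA_real_
  clin_fields <- c("bmi", "wc", "glucose", "hba1c", "sbp", "dbp", "tg", "hdl")
  participants[miss_masld, clin_fields] <- NA_real_
  participants[miss_masld, c("antihtn_tx", "lipid_tx", "antidm_tx", "diabetes_hx")] <- NA
  participants$alcohol_drinks_per_day[miss_alc] <- NA_real_
  participants$alcohol_days_per_week[miss_alc] <- NA_real_
  participants$alcohol_years[miss_alc] <- NA_real_

  truth <- list(seed = config$seed, intercept = alpha,
                steatosis_target = p_star,
                prevalence_target = config$prevalence_target,
                cryptogenic_frac = cf,
                true_links = config$true_links,
                covariate_effects = config$covariate_effects,
                pollutant_means = as.list(config$pollutant_means),
                pollutant_sds = as.list(config$pollutant_sds))
  list(participants = participants, exposure = exposure_long, truth = truth)
}

#' Write / read a generator truth record as JSON
#'
#' @param truth Truth list from [generate_cohort()].
#' @param path File path.
#' @return `read_truth` returns the truth list with `true_link` classes
#'   restored.
#' @export
write_truth <- function(truth, path) {
  truth$true_links <- lapply(truth$true_links, unclass)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$true_links <- lapply(truth$true_links, function(lk) {
    structure(list(shape = lk$shape,
                   cutpoint = lk$cutpoint,
                   slope_below = lk$slope_below %||% 0,
                   slope_above = lk$slope_above %||% 0,
                   jump = lk$jump %||% 0,
                   knots = lk$knots, coefs = lk$coefs),
              class = "true_link")
  })
  truth
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hand-enumerated exclusion-cascade fixture
#'
#' A small deterministic participant table in which every exclusion rule is
#' triggered by a known number of records, each triggering exactly one rule,
#' for testing the cascade's sequential first-trigger semantics.
#'
#' @param seed Integer seed controlling the cosmetic jitter of clinical
#'   values (counts are fixed by construction).
#' @return List with `participants` (100 rows) and `truth` (data frame of
#'   expected per-rule exclusion counts plus `n_retained`).
#' @export
generate_exclusion_fixture <- function(seed = 1L) {
  set.seed(seed)
  counts <- c(missing_exposure_or_sono = 4L, duplicate_checkup = 3L,
              age_under_18 = 3L, missing_masld_fields = 5L,
              missing_alcohol = 4L, cirrhosis_or_hcc = 2L, hepatitis = 4L,
              excess_alcohol = 3L, sono_abnormality = 2L,
              cryptogenic_sld = 3L)
  n_clean <- 100L - sum(counts)  # 67 retained

  base_row <- function(id, date) {
    data.frame(id = id, checkup_date = as.Date(date),
               enrollment_year = as.integer(format(as.Date(date), "%Y")),
               age = 45, sex = "male", marriage = "married",
               education = "college_plus", income = "lt_28k",
               smoking = "never", alcohol_status = "never",
               veg_intake = "moderate", fruit_intake = "moderate",
               sugary_intake = "moderate", fried_intake = "moderate",
               regular_exercise = TRUE,
               alcohol_drinks_per_day = 0, alcohol_days_per_week = 0,
               alcohol_years = 0,
               bmi = 25, wc = 85, glucose = 90, hba1c = 5.3, sbp = 118,
               dbp = 72, tg = 100, hdl = 55, ldl = 110, chol = 185, alt = 20,
               antihtn_tx = FALSE, lipid_tx = FALSE, antidm_tx = FALSE,
               diabetes_hx = FALSE, cirrhosis_hx = FALSE, hcc_hx = FALSE,
               hepatitis_hx = FALSE, steatosis_on_us = FALSE,
               sig_sono_abnormality = FALSE,
               pm25 = 30, pm10 = 50, co = 700, o3 = 52, so2 = 10, no2 = 37,
               exposure_missing = FALSE, stringsAsFactors = FALSE)
  }
  rows <- list(); id <- 0L
  add <- function(mod) {
    id <<- id + 1L
    r <- base_row(id, as.Date("2012-01-01") + id)
    r <- mod(r)
    rows[[length(rows) + 1L]] <<- r
  }
  for (i in seq_len(n_clean)) add(function(r) {
    r$steatosis_on_us <- i %% 2L == 0L  # alternate MASLD / no MASLD
    r
  })
  for (i in seq_len(counts[["missing_exposure_or_sono"]])) add(function(r) {
    if (i %% 2L == 0L) r[.pollutants] <- NA_real_ else r$steatosis_on_us <- NA
    r$exposure_missing <- i %% 2L == 0L
    r
  })
  # duplicates: re-use the first three clean ids with later checkup dates
  for (i in 1:3) {
    r <- base_row(i, as.Date("2015-06-01") + i)
    rows[[length(rows) + 1L]] <- r
  }
  for (i in seq_len(counts[["age_under_18"]])) add(function(r) { r$age <- 16; r })
  for (i in seq_len(counts[["missing_masld_fields"]])) add(function(r) {
    r$steatosis_on_us <- TRUE
    r$bmi <- NA; r$wc <- NA; r$glucose <- NA; r$hba1c <- NA
    r$sbp <- NA; r$dbp <- NA; r$tg <- NA; r$hdl <- NA
    r$antihtn_tx <- NA; r$lipid_tx <- NA; r$antidm_tx <- NA; r$diabetes_hx <- NA
    r
  })
  for (i in seq_len(counts[["missing_alcohol"]])) add(function(r) {
    r$alcohol_drinks_per_day <- NA; r
  })
  for (i in seq_len(counts[["cirrhosis_or_hcc"]])) add(function(r) {
    if (i == 1L) r$cirrhosis_hx <- TRUE else r$hcc_hx <- TRUE
    r
  })
  for (i in seq_len(counts[["hepatitis"]])) add(function(r) { r$hepatitis_hx <- TRUE; r })
  for (i in seq_len(counts[["excess_alcohol"]])) add(function(r) {
    r$alcohol_status <- "current"
    r$alcohol_drinks_per_day <- 3; r$alcohol_days_per_week <- 5
    r$alcohol_years <- 10
    r
  })
  for (i in seq_len(counts[["sono_abnormality"]])) add(function(r) {
    r$sig_sono_abnormality <- TRUE; r
  })
  for (i in seq_len(counts[["cryptogenic_sld"]])) add(function(r) {
    r$steatosis_on_us <- TRUE
    r$bmi <- 21; r$wc <- 80; r$glucose <- 90; r$hba1c <- 5.2
    r$sbp <- 115; r$dbp <- 70; r$tg <- 90; r$hdl <- 55
    r
  })
  participants <- do.call(rbind, rows)
  rownames(participants) <- NULL
  truth <- data.frame(rule = names(counts), n_excluded = as.integer(unname(counts)))
  list(participants = participants,
       truth = truth, n_input = nrow(participants), n_retained = n_clean)
}
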