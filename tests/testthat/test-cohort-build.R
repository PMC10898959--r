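base_record <- function(...) {
  r <- data.frame(steatosis_on_us = TRUE, sex = "male", bmi = 20, wc = 80,
                  glucose = 90, hba1c = 5.2, sbp = 115, dbp = 70, tg = 100,
                  hdl = 55, diabetes_hx = FALSE, antidm_tx = FALSE,
                  antihtn_tx = FALSE, lipid_tx = FALSE,
                  stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) r[[nm]] <- mods[[nm]]
  r
}

test_that("MASLD classification implements the five cardiometabolic criteria", {
  # BMI threshold is inclusive at 23
  lab <- classify_masld(base_record(bmi = 23.0))
  expect_equal(as.character(lab$category), "masld")
  expect_true(lab$crit1)

  # steatosis with zero criteria is cryptogenic
  lab <- classify_masld(base_record())
  expect_equal(as.character(lab$category), "cryptogenic_sld")

  # no steatosis is never MASLD, whatever the criteria
  lab <- classify_masld(base_record(steatosis_on_us = FALSE, bmi = 30))
  expect_equal(as.character(lab$category), "no_masld")

  # sex-specific cuts: WC and HDL
  expect_true(classify_masld(base_record(wc = 95))$crit1)
  expect_false(classify_masld(base_record(sex = "female", wc = 79, hdl = 60))$crit1)
  expect_true(classify_masld(base_record(sex = "female", wc = 81))$crit1)
  expect_true(classify_masld(base_record(sex = "female", hdl = 50))$crit5)
  expect_false(classify_masld(base_record(hdl = 41))$crit5)

  # treatment flags count toward their criteria
  expect_true(classify_masld(base_record(lipid_tx = TRUE))$crit4)
  expect_true(classify_masld(base_record(antihtn_tx = TRUE))$crit3)
  expect_true(classify_masld(base_record(dbp = 85))$crit3)

  # a missing field needed to decide -> undetermined; but another criterion
  # being true decides the category despite the missing field
  expect_equal(as.character(classify_masld(base_record(bmi = NA))$category),
               "undetermined")
  expect_equal(as.character(classify_masld(base_record(bmi = NA, tg = 200))$category),
               "masld")
  expect_equal(as.character(classify_masld(base_record(steatosis_on_us = NA))$category),
               "undetermined")
})

test_that("turning any criterion on never demotes a steatotic MASLD case", {
  flips <- list(base_record(bmi = 24), base_record(glucose = 110),
                base_record(sbp = 135), base_record(tg = 160),
                base_record(hdl = 39))
  for (extra in list(c(bmi = 30), c(glucose = 150), c(sbp = 160), c(tg = 300))) {
    for (r in flips) {
      r2 <- r; r2[[names(extra)]] <- extra
      expect_equal(as.character(classify_masld(r2)$category), "masld")
    }
  }
})

test_that("excess alcohol requires all three components jointly", {
  expect_true(classify_excess_alcohol(2, 3, 2))
  expect_false(classify_excess_alcohol(1, 7, 10))
  expect_false(classify_excess_alcohol(2, 2, 10))
  expect_false(classify_excess_alcohol(2, 3, 1))
  expect_true(is.na(classify_excess_alcohol(2, NA, 2)))
  expect_true(is.na(classify_excess_alcohol(NA, 7, 10)))
})

test_that("the exclusion cascade reproduces the hand-enumerated fixture", {
  fx <- generate_exclusion_fixture(seed = 1)
  res <- apply_exclusions(fx$participants)
  got <- res$cascade$steps
  expect_equal(got$rule, fx$truth$rule)
  expect_equal(got$n_excluded, fx$truth$n_excluded)
  expect_equal(res$cascade$n_retained, fx$n_retained)
  # conservation
  expect_equal(res$cascade$n_input,
               sum(got$n_excluded) + res$cascade$n_retained)
  expect_equal(nrow(res$cohort), res$cascade$n_retained)
})

test_that("a cohort with no triggering records passes through unchanged", {
  fx <- generate_exclusion_fixture(seed = 1)
  clean <- fx$participants[1:40, ]
  res <- apply_exclusions(clean)
  expect_equal(res$cascade$n_retained, 40L)
  expect_true(all(res$cascade$steps$n_excluded == 0L))
})

test_that("cascade bookkeeping validates its arithmetic", {
  cc <- new_exclusion_cascade(100, c(a = 10, b = 5))
  expect_equal(cc$n_retained, 85L)
  expect_error(new_exclusion_cascade(10, c(a = 20)), "more records")
})

test_that("window averages use the trailing calendar months before the index", {
  months <- sprintf("2015-%02d", 1:12)
  months <- c(sprintf("2014-%02d", 1:12), months, sprintf("2016-%02d", 1:12))
  vals <- rep(10, 36)
  expect_equal(window_average(months, vals, as.Date("2017-01-15"), 3), 10)
  expect_equal(window_average(months, vals, "2017-01", 3), 10)
  vals2 <- 1:36
  expect_equal(window_average(months, vals2, "2017-01", 3), 18.5)
  # the index month itself is excluded from the window
  m37 <- c(months, "2017-01")
  expect_equal(window_average(m37, c(vals2, 1e6), "2017-01", 3), 18.5)
  # 35 of 36 months (>= 90% coverage): mean of available months
  expect_equal(window_average(months[-7], vals2[-7], "2017-01", 3),
               mean(vals2[-7]))
  # below coverage -> missing
  expect_true(is.na(window_average(months[1:30], vals2[1:30], "2017-01", 3)))
  # order invariance and linearity
  perm <- sample(36)
  expect_equal(window_average(months[perm], vals2[perm], "2017-01", 3), 18.5)
  expect_equal(window_average(months, 2 * vals2 + 1, "2017-01", 3), 2 * 18.5 + 1)
})

test_that("add_window_averages merges per-pollutant means and flags gaps", {
  months <- c(sprintf("2013-%02d", 1:12), sprintf("2014-%02d", 1:12),
              sprintf("2015-%02d", 1:12))
  expo <- rbind(
    data.frame(participant_id = 1, pollutant = "pm25", month = months, value = 30),
    data.frame(participant_id = 1, pollutant = "no2", month = months, value = 40),
    data.frame(participant_id = 2, pollutant = "pm25", month = months[1:20], value = 30),
    data.frame(participant_id = 2, pollutant = "no2", month = months, value = 40))
  parts <- data.frame(id = 1:2, checkup_date = as.Date("2016-01-10"))
  out <- add_window_averages(parts, expo, years = 3)
  expect_equal(out$pm25, c(30, NA))
  expect_equal(out$no2, c(40, 40))
  expect_equal(out$exposure_missing, c(FALSE, TRUE))
})

test_that("covariate encoding handles unreported and modal imputation", {
  df <- data.frame(age = c(30, 40, 50, 60),
                   marriage = c("married", NA, "single", "married"),
                   smoking = c("never", "never", NA, "current"),
                   regular_exercise = c(TRUE, FALSE, TRUE, NA),
                   enrollment_year = c(2010L, 2011L, 2010L, 2011L),
                   stringsAsFactors = FALSE)
  enc <- encode_covariates(df, vars = c("age", "marriage", "smoking",
                                        "regular_exercise", "enrollment_year"))
  M <- enc$matrix
  expect_equal(unname(M[, "age"]), df$age)            # numeric passes through
  expect_equal(unname(M[2, "marriage_unreported"]), 1) # explicit category
  expect_equal(unname(M[3, "smoking_current"]), 0)     # imputed to mode "never"
  expect_equal(unname(M[4, "regular_exercise_yes"]), 1) # mode of exercise = TRUE
  expect_true("enrollment_year_2011" %in% colnames(M))
  d <- enc$dictionary
  expect_equal(d$level[d$variable == "marriage" & d$reference], "single")
  expect_equal(d$level[d$variable == "smoking" & d$reference], "never")
  expect_error(encode_covariates(data.frame(age = c(NA_real_, NA_real_)),
                                 vars = "age"), "entirely missing")
})

test_that("descriptive table matches direct two-pass summaries", {
  cfg <- method_config(2000, null_links(), seed = 77)
  p <- labelled_cohort(cfg)
  tab <- descriptive_table(p, vars = c("age", "sex", "bmi", "pm25"))
  # means/SDs against direct computation
  r <- tab[tab$variable == "bmi", ]
  expect_equal(r$mean_masld, mean(p$bmi[p$masld]), tolerance = 1e-12)
  expect_equal(r$sd_masld, sd(p$bmi[p$masld]), tolerance = 1e-12)
  expect_equal(r$mean_no_masld, mean(p$bmi[!p$masld]), tolerance = 1e-12)
  # stratum percentages of a categorical variable sum to 100
  sexrows <- tab[tab$variable == "sex", ]
  expect_equal(sum(sexrows$pct_masld), 100, tolerance = 0.1)
  expect_equal(sum(sexrows$pct_no_masld), 100, tolerance = 0.1)
  expect_equal(sexrows$n_masld[sexrows$level == "male"],
               sum(p$sex == "male" & p$masld))
})
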