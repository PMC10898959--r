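# Cohort construction: MASLD classification, excess-alcohol rule, the
# exclusion cascade, trailing-window exposure averaging, covariate encoding
# and descriptive summaries.

.crit_or_na <- function(...) {
  # logical OR that returns TRUE if any component is TRUE, otherwise NA if
  # any component is NA, otherwise FALSE (a criterion met on one branch is
  # met even when another branch is unrecorded)
  m <- cbind(...)
  any_true <- rowSums(m, na.rm = TRUE) > 0
  ifelse(any_true, TRUE, ifelse(rowSums(is.na(m)) > 0, NA, FALSE))
}

#' Classify MASLD from steatosis and the five cardiometabolic criteria
#'
#' MASLD requires sonographic hepatic steatosis plus at least one of five
#' cardiometabolic criteria:
#' \enumerate{
#'   \item BMI >= 23 kg/m2, or waist circumference > 94 cm (men) / > 80 cm
#'     (women);
#'   \item fasting glucose >= 100 mg/dL, or HbA1c >= 5.7\%, or diabetes
#'     history or anti-diabetic treatment;
#'   \item blood pressure >= 130/85 mmHg (SBP >= 130 or DBP >= 85) or
#'     antihypertensive treatment;
#'   \item triglycerides >= 150 mg/dL or lipid-lowering treatment;
#'   \item HDL <= 40 mg/dL (men) / <= 50 mg/dL (women) or lipid-lowering
#'     treatment.
#' }
#' Steatosis with all five criteria false is cryptogenic steatotic liver
#' disease.  A record is `undetermined` when a field needed to decide the
#' category is missing.
#'
#' @param records Data frame with columns `steatosis_on_us` (logical),
#'   `sex` (`"male"`/`"female"`), `bmi`, `wc`, `glucose`, `hba1c`, `sbp`,
#'   `dbp`, `tg`, `hdl` (numeric), and logical treatment/history flags
#'   `diabetes_hx`, `antidm_tx`, `antihtn_tx`, `lipid_tx`.
#' @return Data frame with logical columns `steatosis`, `crit1`..`crit5`
#'   and a factor `category` in
#'   `{"masld", "no_masld", "cryptogenic_sld", "undetermined"}`.
#' @export
classify_masld <- function(records) {
  male <- records$sex == "male"
  crit1 <- .crit_or_na(records$bmi >= 23,
                       ifelse(male, records$wc > 94, records$wc > 80))
  crit2 <- .crit_or_na(records$glucose >= 100, records$hba1c >= 5.7,
                       records$diabetes_hx, records$antidm_tx)
  crit3 <- .crit_or_na(records$sbp >= 130, records$dbp >= 85,
                       records$antihtn_tx)
  crit4 <- .crit_or_na(records$tg >= 150, records$lipid_tx)
  crit5 <- .crit_or_na(ifelse(male, records$hdl <= 40, records$hdl <= 50),
                       records$lipid_tx)
  any_crit <- .crit_or_na(crit1, crit2, crit3, crit4, crit5)
  steat <- records$steatosis_on_us
  category <- ifelse(is.na(steat), "undetermined",
    ifelse(!steat, "no_masld",
      ifelse(is.na(any_crit), "undetermined",
        ifelse(any_crit, "masld", "cryptogenic_sld"))))
  data.frame(steatosis = steat,
             crit1 = crit1, crit2 = crit2, crit3 = crit3,
             crit4 = crit4, crit5 = crit5,
             category = factor(category,
               levels = c("masld", "no_masld", "cryptogenic_sld", "undetermined")))
}

#' Excess-alcohol rule
#'
#' TRUE when a participant reports two or more alcoholic drinks per day on
#' three or more days a week for more than one year; NA when any component
#' is missing.
#'
#' @param drinks_per_day,days_per_week,duration_years Numeric vectors.
#' @return Logical vector (with NA for incomplete reports).
#' @export
classify_excess_alcohol <- function(drinks_per_day, days_per_week, duration_years) {
  out <- drinks_per_day >= 2 & days_per_week >= 3 & duration_years > 1
  out[is.na(drinks_per_day) | is.na(days_per_week) | is.na(duration_years)] <- NA
  out
}

#' Construct an exclusion-cascade record
#'
#' Book-keeping object for sequential exclusions: rule names with per-rule
#' excluded counts, the input size and the retained size
#' (`n_input - sum(counts)`).
#'
#' @param n_input Number of records entering the cascade.
#' @param counts Named integer vector of per-rule exclusion counts, in
#'   application order.
#' @return Object of class `exclusion_cascade`.
#' @export
new_exclusion_cascade <- function(n_input, counts) {
  stopifnot(n_input >= 0, all(counts >= 0), !is.null(names(counts)))
  retained <- n_input - sum(counts)
  if (retained < 0) stop("excluded more records than supplied")
  structure(list(n_input = as.integer(n_input),
                 steps = data.frame(rule = names(counts),
                                    n_excluded = as.integer(unname(counts))),
                 n_retained = as.integer(retained)),
            class = "exclusion_cascade")
}

#' @export
print.exclusion_cascade <- function(x, ...) {
  cat(sprintf("<exclusion_cascade> %d records in\n", x$n_input))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  - %-28s %7d\n", x$steps$rule[i], x$steps$n_excluded[i]))
  }
  cat(sprintf("  = retained %d\n", x$n_retained))
  invisible(x)
}

# The fixed rule order of the enrollment flow diagram.
.exclusion_rules <- c(
  "missing_exposure_or_sono", "duplicate_checkup", "age_under_18",
  "missing_masld_fields", "missing_alcohol", "cirrhosis_or_hcc",
  "hepatitis", "excess_alcohol", "sono_abnormality", "cryptogenic_sld")

#' Apply the enrollment exclusion cascade
#'
#' Sequentially removes records in the fixed flow-diagram order: missing
#' exposure/sonography data, duplicate checkups (the earliest record per
#' participant is kept), age < 18, missing MASLD-defining fields, missing
#' alcohol information, cirrhosis/HCC history, viral or other hepatitis,
#' excess alcohol intake, significant sonographic abnormality, and
#' cryptogenic steatotic liver disease.  Each record is counted once, at the
#' first rule it triggers.
#'
#' @param records Participant data frame (see [classify_masld()] for the
#'   clinical columns) with additionally `id`, `checkup_date`, `age`,
#'   `exposure_missing`, `cirrhosis_hx`, `hcc_hx`, `hepatitis_hx`,
#'   `sig_sono_abnormality` and the three alcohol-quantity columns
#'   `alcohol_drinks_per_day`, `alcohol_days_per_week`, `alcohol_years`.
#' @return List with `cohort` (retained records, plus a logical `masld`
#'   column) and `cascade` (an [new_exclusion_cascade()] object).
#' @export
apply_exclusions <- function(records) {
  if (nrow(records) == 0L) stop("empty input")
  lab <- classify_masld(records)
  excess <- classify_excess_alcohol(records$alcohol_drinks_per_day,
                                    records$alcohol_days_per_week,
                                    records$alcohol_years)
  ord <- order(records$checkup_date)
  dup <- logical(nrow(records))
  dup[ord] <- duplicated(records$id[ord])

  flags <- cbind(
    missing_exposure_or_sono = records$exposure_missing %in% TRUE |
      is.na(records$steatosis_on_us),
    duplicate_checkup = dup,
    age_under_18 = records$age < 18,
    missing_masld_fields = lab$category == "undetermined" &
      !is.na(records$steatosis_on_us),
    missing_alcohol = is.na(excess),
    cirrhosis_or_hcc = records$cirrhosis_hx %in% TRUE | records$hcc_hx %in% TRUE,
    hepatitis = records$hepatitis_hx %in% TRUE,
    excess_alcohol = excess %in% TRUE,
    sono_abnormality = records$sig_sono_abnormality %in% TRUE,
    cryptogenic_sld = lab$category == "cryptogenic_sld")
  flags[is.na(flags)] <- FALSE

  first_rule <- apply(flags, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else 0L
  })
  counts <- vapply(seq_along(.exclusion_rules),
                   function(i) sum(first_rule == i), 0L)
  names(counts) <- .exclusion_rules
  keep <- first_rule == 0L
  cohort <- records[keep, , drop = FALSE]
  cohort$masld <- lab$category[keep] == "masld"
  rownames(cohort) <- NULL
  list(cohort = cohort,
       cascade = new_exclusion_cascade(nrow(records), counts))
}

#' Trailing-window average of a monthly exposure series
#'
#' Arithmetic mean of the `years * 12` calendar months strictly before the
#' index month.  If fewer than `coverage` of the window months carry a value
#' the average is reported missing (feeding the missing-exposure exclusion).
#'
#' @param months Character vector `"YYYY-MM"` (or Dates) of the series.
#' @param values Numeric concentrations, same length as `months`.
#' @param index_date Date (or `"YYYY-MM"`) of the index checkup; its own
#'   month is excluded from the window.
#' @param years Window length in years (1 to 4).
#' @param coverage Minimum fraction of window months required (default 0.9).
#' @return The window mean, or `NA_real_` under insufficient coverage.
#' @export
window_average <- function(months, values, index_date, years, coverage = 0.9) {
  stopifnot(years >= 1, length(months) == length(values))
  midx <- .month_index(months)
  idx0 <- .month_index(index_date)
  span <- years * 12L
  in_win <- midx >= idx0 - span & midx <= idx0 - 1L
  v <- values[in_win]
  v <- v[is.finite(v)]
  if (length(v) < coverage * span) return(NA_real_)
  mean(v)
}

# months since year 0 for "YYYY-MM" strings or Date objects
.month_index <- function(m) {
  if (inherits(m, "Date")) {
    lt <- as.POSIXlt(m)
    return((lt$year + 1900L) * 12L + lt$mon)
  }
  yr <- as.integer(substr(m, 1L, 4L))
  mo <- as.integer(substr(m, 6L, 7L))
  yr * 12L + (mo - 1L)
}

#' Per-participant trailing-window exposure averages
#'
#' Applies [window_average()] to a long-format monthly exposure table and
#' merges one column per pollutant onto the participant table.
#'
#' @param participants Data frame with `id` and `checkup_date`.
#' @param exposure Long data frame with columns `participant_id`,
#'   `pollutant`, `month` (`"YYYY-MM"`), `value`.
#' @param years Window length in years (default 3).
#' @param coverage Minimum fraction of window months required (default 0.9).
#' @return `participants` with one numeric column per pollutant and a
#'   logical `exposure_missing` column (TRUE when any pollutant window
#'   failed coverage).
#' @export
add_window_averages <- function(participants, exposure, years = 3, coverage = 0.9) {
  polls <- sort(unique(exposure$pollutant))
  key <- split(seq_len(nrow(exposure)), exposure$participant_id)
  res <- matrix(NA_real_, nrow = nrow(participants), ncol = length(polls),
                dimnames = list(NULL, polls))
  for (i in seq_len(nrow(participants))) {
    rows <- key[[as.character(participants$id[i])]]
    if (is.null(rows)) next
    sub <- exposure[rows, , drop = FALSE]
    for (p in polls) {
      sp <- sub[sub$pollutant == p, , drop = FALSE]
      res[i, p] <- window_average(sp$month, sp$value,
                                  participants$checkup_date[i], years,
                                  coverage = coverage)
    }
  }
  out <- cbind(participants, as.data.frame(res))
  out$exposure_missing <- apply(res, 1L, function(r) any(is.na(r)))
  out
}

# covariates adjusted for throughout the modelling stages
.default_covariates <- c("age", "sex", "marriage", "education", "income",
                         "alcohol_status", "smoking", "fried_intake",
                         "veg_intake", "fruit_intake", "sugary_intake",
                         "regular_exercise", "enrollment_year")

.reference_levels <- list(
  sex = "female", marriage = "single", education = "college_plus",
  income = "lt_28k", smoking = "never", alcohol_status = "never",
  veg_intake = "seldom", fruit_intake = "seldom", sugary_intake = "seldom",
  fried_intake = "seldom")

# socio-economic factors whose missing values become an explicit category
.unreported_vars <- c("marriage", "education", "income")

#' Encode adjustment covariates as a numeric model matrix
#'
#' Missing marriage/education/income become an explicit `"unreported"`
#' level; missing values in the other categorical covariates are imputed
#' with the modal category.  Categorical variables are dummy-coded against
#' fixed reference levels (female, single, college-or-higher education,
#' lowest income band, never-smoker, never-drinker, seldom intake, no
#' regular exercise); age is continuous and enrollment year is categorical.
#' Diabetes, hypertension and dyslipidemia are deliberately not encodable
#' here: they are part of the outcome definition and stay unadjusted.
#'
#' @param cohort Post-exclusion cohort data frame.
#' @param vars Covariate columns to encode (default: the full adjustment
#'   set used by the modelling stages).
#' @return List with `matrix` (numeric, no intercept column) and
#'   `dictionary` (data frame mapping matrix columns to variables/levels,
#'   with reference levels flagged).
#' @export
encode_covariates <- function(cohort, vars = .default_covariates) {
  stopifnot(all(vars %in% names(cohort)))
  pieces <- list(); dict <- list()
  for (v in vars) {
    col <- cohort[[v]]
    if (is.numeric(col) && v != "enrollment_year") {
      if (all(is.na(col))) stop("covariate '", v, "' is entirely missing")
      pieces[[v]] <- matrix(col, ncol = 1L, dimnames = list(NULL, v))
      dict[[v]] <- data.frame(column = v, variable = v, level = NA, reference = FALSE)
      next
    }
    if (is.logical(col)) col <- ifelse(col, "yes", "no")
    col <- as.character(col)
    if (v %in% .unreported_vars) {
      col[is.na(col)] <- "unreported"
    } else if (anyNA(col)) {
      tab <- table(col)
      if (length(tab) == 0L) stop("covariate '", v, "' is entirely missing")
      col[is.na(col)] <- names(tab)[which.max(tab)]
    }
    ref <- .reference_levels[[v]]
    if (v == "regular_exercise") ref <- "no"
    lev <- sort(unique(col))
    if (!is.null(ref) && ref %in% lev) lev <- c(ref, setdiff(lev, ref))
    if (v == "enrollment_year") lev <- sort(lev)
    f <- factor(col, levels = lev)
    if (nlevels(f) < 2L) {
      dict[[v]] <- data.frame(column = character(), variable = character(),
                              level = character(), reference = logical())
      next  # constant covariate carries no information
    }
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(v, "_", lev[-1L])
    pieces[[v]] <- mm
    dict[[v]] <- rbind(
      data.frame(column = NA_character_, variable = v, level = lev[1L], reference = TRUE),
      data.frame(column = colnames(mm), variable = v, level = lev[-1L], reference = FALSE))
  }
  list(matrix = do.call(cbind, pieces), dictionary = do.call(rbind, c(dict, make.row.names = FALSE)))
}

#' Descriptive cohort summary stratified by MASLD status
#'
#' Mean +/- SD for continuous variables and n (percent within stratum) for
#' categorical variables, for participants with and without MASLD.
#'
#' @param cohort Post-exclusion cohort with a logical `masld` column.
#' @param vars Columns to summarize (default: every column except
#'   identifiers and `masld`).
#' @return Data frame with columns `variable`, `level`, `stat_no_masld`,
#'   `stat_masld` plus numeric helper columns (`mean`/`sd` or `n`/`pct` per
#'   stratum).
#' @export
descriptive_table <- function(cohort, vars = NULL) {
  stopifnot("masld" %in% names(cohort))
  if (is.null(vars)) {
    vars <- setdiff(names(cohort), c("id", "checkup_date", "masld", "exposure_missing"))
  }
  strata <- list(no_masld = cohort[!cohort$masld, , drop = FALSE],
                 masld = cohort[cohort$masld, , drop = FALSE])
  rows <- list()
  for (v in vars) {
    col <- cohort[[v]]
    if (is.numeric(col)) {
      m <- vapply(strata, function(s) mean(s[[v]], na.rm = TRUE), 0)
      sdv <- vapply(strata, function(s) stats::sd(s[[v]], na.rm = TRUE), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_,
        mean_no_masld = m[["no_masld"]], sd_no_masld = sdv[["no_masld"]],
        mean_masld = m[["masld"]], sd_masld = sdv[["masld"]],
        n_no_masld = NA_real_, pct_no_masld = NA_real_,
        n_masld = NA_real_, pct_masld = NA_real_,
        stat_no_masld = sprintf("%.1f ± %.1f", m[["no_masld"]], sdv[["no_masld"]]),
        stat_masld = sprintf("%.1f ± %.1f", m[["masld"]], sdv[["masld"]]))
    } else {
      if (is.logical(col)) col <- ifelse(col, "yes", "no")
      for (lv in sort(unique(stats::na.omit(as.character(col))))) {
        cnt <- vapply(strata, function(s) {
          sc <- s[[v]]
          if (is.logical(sc)) sc <- ifelse(sc, "yes", "no")
          sum(sc == lv, na.rm = TRUE)
        }, 0)
        tot <- vapply(strata, function(s) sum(!is.na(s[[v]])), 0)
        pct <- 100 * cnt / pmax(tot, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv,
          mean_no_masld = NA_real_, sd_no_masld = NA_real_,
          mean_masld = NA_real_, sd_masld = NA_real_,
          n_no_masld = cnt[["no_masld"]], pct_no_masld = pct[["no_masld"]],
          n_masld = cnt[["masld"]], pct_masld = pct[["masld"]],
          stat_no_masld = sprintf("%d (%.1f)", cnt[["no_masld"]], pct[["no_masld"]]),
          stat_masld = sprintf("%d (%.1f)", cnt[["masld"]], pct[["masld"]]))
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
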