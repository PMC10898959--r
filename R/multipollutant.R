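# Joint six-pollutant logistic model (plus categorized, all-linear and
# subset variants), segment-wise adjusted odds ratios, collinearity
# diagnostics and adjusted predicted curves.

.cohort_fingerprint <- function(y) {
  y <- as.integer(y)
  c(n = length(y), cases = sum(y),
    checksum = sum((seq_along(y) %% 997L) * y) %% 2147483647)
}

.mp_glm <- function(X, y, specs, col_map, exposures, extra = list()) {
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  if (anyNA(fit$coefficients)) stop("rank-deficient multipollutant design")
  if (!fit$converged) warning("multipollutant fit did not converge")
  k <- length(fit$coefficients)
  ll <- -fit$aic / 2 + k
  vc <- .irls_vcov(X, fit)
  structure(c(list(specs = specs, coef = fit$coefficients, vcov = vc,
                   loglik = ll, n_params = k, aic = fit$aic,
                   col_map = col_map, design_means = colMeans(X),
                   exposures = exposures,
                   fingerprint = .cohort_fingerprint(y),
                   converged = fit$converged), extra),
            class = "mp_model")
}

#' @export
print.mp_model <- function(x, ...) {
  cat(sprintf("<mp_model> %d pollutants, %d parameters, AIC %.1f\n",
              length(x$col_map), x$n_params, x$aic))
  for (p in names(x$specs)) {
    s <- x$specs[[p]]
    cat(sprintf("  %-5s %s\n", p,
                if (inherits(s, "link_spec")) s$kind else as.character(s)))
  }
  invisible(x)
}

#' Fit the joint multi-pollutant logistic model
#'
#' One logistic regression containing every included pollutant
#' simultaneously, each encoded through its [link_spec()], plus adjustment
#' covariates.  Diabetes, hypertension and dyslipidemia are never part of
#' the covariates: they belong to the outcome definition.
#'
#' @param cohort Data frame with one column per pollutant (3-year mean
#'   exposure) and a logical/0-1 `masld` outcome column.
#' @param specs Named list of [link_spec()] objects (names = pollutant
#'   columns).
#' @param covariates Optional numeric covariate matrix (e.g. from
#'   [encode_covariates()]).
#' @param include Pollutants to include (default: all names of `specs`).
#' @return An object of class `mp_model` with coefficients, covariance,
#'   log-likelihood, AIC, per-pollutant column map and design means.
#' @export
fit_multipollutant <- function(cohort, specs, covariates = NULL,
                               include = names(specs)) {
  stopifnot(all(include %in% names(specs)), "masld" %in% names(cohort))
  y <- as.integer(cohort$masld)
  X <- matrix(1, nrow(cohort), 1L, dimnames = list(NULL, "(Intercept)"))
  col_map <- list()
  exposures <- matrix(NA_real_, nrow(cohort), length(include),
                      dimnames = list(NULL, include))
  for (p in include) {
    B <- basis_matrix(cohort[[p]], specs[[p]])
    colnames(B) <- paste0(p, ".", colnames(B))
    col_map[[p]] <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
    exposures[, p] <- cohort[[p]]
  }
  if (!is.null(covariates)) X <- cbind(X, covariates)
  .mp_glm(X, y, specs[include], col_map, exposures)
}

#' Fit the all-linear sensitivity model
#'
#' The multi-pollutant model with a linear link for every pollutant.
#'
#' @inheritParams fit_multipollutant
#' @param pollutants Pollutant column names (default: the six standard
#'   monitored pollutants present in `cohort`).
#' @return An `mp_model`.
#' @export
fit_all_linear <- function(cohort, covariates = NULL,
                           pollutants = intersect(.pollutants, names(cohort))) {
  specs <- lapply(pollutants, function(p) link_spec(p, "linear"))
  names(specs) <- pollutants
  fit_multipollutant(cohort, specs, covariates)
}

#' Fit a subset (leave-pollutants-out) sensitivity model
#'
#' @inheritParams fit_multipollutant
#' @param exclude Pollutant names to drop (e.g. `"pm10"`).
#' @return An `mp_model` over the remaining pollutants.
#' @export
fit_subset <- function(cohort, specs, covariates = NULL, exclude = character()) {
  fit_multipollutant(cohort, specs, covariates,
                     include = setdiff(names(specs), exclude))
}

#' Fit the categorized-exposure model
#'
#' Replaces each pollutant's continuous exposure by indicator segments cut
#' at the supplied inflection points (lowest segment = reference) and fits
#' the joint logistic model.
#'
#' @inheritParams fit_multipollutant
#' @param cutpoints Named list: per pollutant, a numeric vector of 1 or 2
#'   cut locations (ug/m3).
#' @return An `mp_model`; segment odds ratios via [categorized_or()].
#' @export
fit_categorized <- function(cohort, cutpoints, covariates = NULL) {
  stopifnot("masld" %in% names(cohort))
  y <- as.integer(cohort$masld)
  X <- matrix(1, nrow(cohort), 1L, dimnames = list(NULL, "(Intercept)"))
  col_map <- list(); seg_info <- list()
  exposures <- matrix(NA_real_, nrow(cohort), length(cutpoints),
                      dimnames = list(NULL, names(cutpoints)))
  for (p in names(cutpoints)) {
    cuts <- sort(cutpoints[[p]])
    x <- cohort[[p]]
    seg <- findInterval(x, cuts)  # 0 = below first cut (reference)
    tab <- tabulate(seg + 1L, nbins = length(cuts) + 1L)
    if (any(tab == 0L)) stop("empty exposure segment for ", p)
    # one indicator per non-reference segment: seg == k
    D <- sapply(seq_along(cuts), function(k) as.numeric(seg == k))
    colnames(D) <- paste0(p, ".seg", seq_along(cuts))
    col_map[[p]] <- ncol(X) + seq_len(ncol(D))
    seg_info[[p]] <- cuts
    X <- cbind(X, D)
    exposures[, p] <- x
  }
  if (!is.null(covariates)) X <- cbind(X, covariates)
  specs <- as.list(rep("categorized", length(cutpoints)))
  names(specs) <- names(cutpoints)
  .mp_glm(X, y, specs, col_map, exposures, extra = list(cutpoints = seg_info))
}

#' Segment odds-ratio table for a categorized model
#'
#' @param model An `mp_model` from [fit_categorized()].
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row per exposure segment: `pollutant`,
#'   `segment`, `aor`, `lo`, `hi` (reference segments have aOR 1 by
#'   construction and NA limits).
#' @export
categorized_or <- function(model, conf_level = 0.95) {
  stopifnot(!is.null(model$cutpoints))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  for (p in names(model$cutpoints)) {
    cuts <- model$cutpoints[[p]]
    labs <- c(sprintf("< %g", cuts[1L]),
              if (length(cuts) == 2L) sprintf("%g to %g", cuts[1L], cuts[2L]),
              sprintf(">= %g", cuts[length(cuts)]))
    rows[[length(rows) + 1L]] <- data.frame(
      pollutant = p, segment = labs[1L], aor = 1, lo = NA_real_, hi = NA_real_)
    for (k in seq_along(cuts)) {
      j <- model$col_map[[p]][k]
      b <- model$coef[j]; se <- sqrt(model$vcov[j, j])
      rows[[length(rows) + 1L]] <- data.frame(
        pollutant = p, segment = labs[k + 1L],
        aor = exp(b), lo = exp(b - z * se), hi = exp(b + z * se))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Per-unit adjusted odds ratio within an exposure segment
#'
#' For linear links the aOR per 1 ug/m3 is `exp(coefficient)` everywhere.
#' For a threshold link the segment below the cutpoint is structurally flat:
#' the aOR is exactly 1 with a zero-width interval; above the cutpoint it is
#' `exp(hinge coefficient)`.  For an interaction link the below/above slopes
#' are `b_x` and `b_x + b_interaction` (delta-method CI).  For an RCS link
#' the fitted slope varies over the segment: the reported aOR is
#' `exp` of the average derivative of the fitted logit over the segment,
#' weighted by the observed exposure distribution, with a delta-method CI on
#' the averaged derivative.  `method = "endpoint"` instead uses the chord
#' slope between the segment endpoints.
#'
#' @param model An `mp_model` from [fit_multipollutant()].
#' @param pollutant Pollutant name.
#' @param lower,upper Segment bounds in ug/m3 (may be `-Inf`/`Inf`).
#' @param conf_level Confidence level (default 0.95).
#' @param method `"avg_deriv"` (default) or `"endpoint"` for RCS segments.
#' @return One-row data frame: `pollutant`, `lower`, `upper`, `aor`, `lo`,
#'   `hi`, `structural` (TRUE for the flat threshold baseline).
#' @export
segment_or <- function(model, pollutant, lower, upper, conf_level = 0.95,
                       method = c("avg_deriv", "endpoint")) {
  method <- match.arg(method)
  spec <- model$specs[[pollutant]]
  if (is.null(spec) || !inherits(spec, "link_spec")) {
    stop("no continuous link spec for pollutant ", pollutant)
  }
  idx <- model$col_map[[pollutant]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  row <- function(est, se, structural = FALSE) {
    data.frame(pollutant = pollutant, lower = lower, upper = upper,
               aor = exp(est), lo = exp(est - z * se), hi = exp(est + z * se),
               structural = structural)
  }
  if (spec$kind == "linear") {
    return(row(model$coef[idx], sqrt(model$vcov[idx, idx])))
  }
  if (spec$kind == "threshold") {
    if (upper <= spec$cutpoint) {
      return(data.frame(pollutant = pollutant, lower = lower, upper = upper,
                        aor = 1, lo = 1, hi = 1, structural = TRUE))
    }
    return(row(model$coef[idx], sqrt(model$vcov[idx, idx])))
  }
  if (spec$kind == "interaction") {
    # columns: x, above, x_above
    jx <- idx[1L]; jxa <- idx[3L]
    if (upper <= spec$cutpoint) {
      return(row(model$coef[jx], sqrt(model$vcov[jx, jx])))
    }
    est <- model$coef[jx] + model$coef[jxa]
    se <- sqrt(model$vcov[jx, jx] + model$vcov[jxa, jxa] +
                 2 * model$vcov[jx, jxa])
    return(row(est, se))
  }
  # RCS
  xs <- model$exposures[, pollutant]
  xs <- xs[xs >= lower & xs < upper & is.finite(xs)]
  if (length(xs) == 0L) stop("segment [", lower, ", ", upper,
                             ") outside observed exposure support")
  if (method == "avg_deriv") {
    g <- colMeans(rcs_basis_deriv(xs, spec$knots))
  } else {
    lo_x <- max(lower, min(xs)); hi_x <- min(upper, max(xs))
    B <- rcs_basis(c(lo_x, hi_x), spec$knots)
    g <- (B[2L, ] - B[1L, ]) / (hi_x - lo_x)
  }
  est <- sum(g * model$coef[idx])
  se <- sqrt(drop(t(g) %*% model$vcov[idx, idx, drop = FALSE] %*% g))
  row(est, se)
}

#' Collinearity diagnostics for a design matrix
#'
#' For every column `j`, the R-squared of regressing it on all other
#' columns gives `VIF_j = 1 / (1 - R2_j)` and tolerance `1 / VIF_j`.  Also
#' reports pairwise Pearson correlations with Fisher-z confidence
#' intervals.
#'
#' @param design Numeric matrix (no intercept column needed; one is added
#'   to the auxiliary regressions).
#' @param conf_level Confidence level for the correlation CIs.
#' @return List with `terms` (data frame: `term`, `r_squared`, `tolerance`,
#'   `vif`) and `correlations` (data frame: `var1`, `var2`, `r`, `lo`,
#'   `hi`).  Perfectly collinear columns get tolerance 0 and infinite VIF.
#' @export
collinearity_diagnostics <- function(design, conf_level = 0.95) {
  design <- as.matrix(design)
  p <- ncol(design)
  nm <- colnames(design)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  r2 <- numeric(p)
  for (j in seq_len(p)) {
    yj <- design[, j]
    Xj <- cbind(1, design[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    tss <- sum((yj - mean(yj))^2)
    rss <- sum(fit$residuals^2)
    r2[j] <- if (tss == 0) 1 else 1 - rss / tss
  }
  r2 <- pmin(pmax(r2, 0), 1)
  tol <- 1 - r2
  vif <- ifelse(tol <= .Machine$double.eps^0.5, Inf, 1 / tol)
  tol <- ifelse(is.infinite(vif), 0, tol)
  terms <- data.frame(term = nm, r_squared = r2, tolerance = tol, vif = vif)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- nrow(design)
  pairs <- utils::combn(p, 2L)
  r <- apply(pairs, 2L, function(ij) stats::cor(design[, ij[1L]], design[, ij[2L]]))
  fz <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  correlations <- data.frame(var1 = nm[pairs[1L, ]], var2 = nm[pairs[2L, ]],
                             r = r, lo = tanh(fz - z * se), hi = tanh(fz + z * se))
  list(terms = terms, correlations = correlations)
}

#' Adjusted predicted logit curve for one pollutant
#'
#' Evaluates the model's linear predictor over an exposure grid with every
#' other design column (co-pollutant bases and covariate dummies) fixed at
#' its sample mean -- for categorical dummies this is the observed
#' proportion, the only "mean value" that keeps the prediction inside the
#' model space.
#'
#' @param model An `mp_model` from [fit_multipollutant()].
#' @param pollutant Pollutant name.
#' @param grid Numeric grid of exposure values; must stay within the
#'   observed range extended by `extrapolation_margin` times the range.
#' @param extrapolation_margin Allowed relative extrapolation (default
#'   0.05).
#' @return Data frame of class `predicted_curve`: `exposure`, `logit`.
#' @export
predicted_curve <- function(model, pollutant, grid,
                            extrapolation_margin = 0.05) {
  spec <- model$specs[[pollutant]]
  if (is.null(spec) || !inherits(spec, "link_spec")) {
    stop("no continuous link spec for pollutant ", pollutant)
  }
  xs <- model$exposures[, pollutant]
  rng <- range(xs, na.rm = TRUE)
  margin <- extrapolation_margin * diff(rng)
  if (any(grid < rng[1L] - margin | grid > rng[2L] + margin)) {
    stop("grid extends beyond the observed exposure range (margin ",
         extrapolation_margin, ")")
  }
  idx <- model$col_map[[pollutant]]
  base <- sum(model$design_means[-idx] * model$coef[-idx])
  B <- basis_matrix(grid, spec)
  out <- data.frame(exposure = grid,
                    logit = base + drop(B %*% model$coef[idx]))
  class(out) <- c("predicted_curve", "data.frame")
  out
}

#' Compare models fitted on the same cohort by AIC
#'
#' Refuses to rank models whose cohort fingerprints (size, case count,
#' outcome checksum) differ, since AIC is only comparable on identical
#' data.
#'
#' @param models Named list of `mp_model` objects.
#' @return Data frame sorted by AIC: `model`, `aic`, `delta_aic`,
#'   `n_params`.
#' @export
compare_models <- function(models) {
  stopifnot(length(models) >= 1L, !is.null(names(models)))
  fp <- lapply(models, function(m) m$fingerprint)
  for (i in seq_along(fp)[-1L]) {
    if (!identical(fp[[i]], fp[[1L]])) {
      stop("models were fitted on different cohorts; AIC not comparable")
    }
  }
  aic <- vapply(models, function(m) m$aic, 0)
  out <- data.frame(model = names(models), aic = aic,
                    delta_aic = aic - min(aic),
                    n_params = vapply(models, function(m) m$n_params, 0))
  out <- out[order(out$aic, out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}
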