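# Percentile-binned empirical-logit curves and segmented (broken-stick)
# non-linear least squares for inflection-point estimation.

#' Percentile-binned empirical logit curve
#'
#' Divides the exposure range into quantile bins (equal counts up to ties)
#' and computes, per bin, the mean exposure, the number of observations, the
#' number of cases and the empirical logit
#' `ln((cases + 0.5) / (n - cases + 0.5))`.  The +0.5 continuity correction
#' keeps the logit finite in bins with 0% or 100% prevalence.
#'
#' @param exposure Numeric exposure vector.
#' @param outcome Binary (0/1 or logical) outcome vector.
#' @param n_bins Target number of bins (default 100); ties between identical
#'   exposure values can reduce the realized number of bins.
#' @return An object of class `binned_logit_curve`: a data frame with columns
#'   `bin`, `mean_exposure`, `n`, `cases`, `elogit`.
#' @export
binned_logit <- function(exposure, outcome, n_bins = 100L) {
  outcome <- as.integer(outcome)
  ok <- is.finite(exposure) & !is.na(outcome)
  exposure <- exposure[ok]; outcome <- outcome[ok]
  n <- length(exposure)
  if (n < n_bins) stop("fewer observations (", n, ") than bins (", n_bins, ")")
  if (!all(outcome %in% c(0L, 1L))) stop("outcome must be binary")
  breaks <- unique(stats::quantile(exposure, probs = seq(0, 1, length.out = n_bins + 1L),
                                   type = 7, names = FALSE))
  if (length(breaks) < 2L) stop("all exposures identical; cannot bin")
  bin <- cut(exposure, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  mean_exposure <- as.numeric(tapply(exposure, bin, mean))
  nb    <- as.integer(tapply(exposure, bin, length))
  cases <- as.integer(tapply(outcome, bin, sum))
  out <- data.frame(bin = sort(unique(bin)),
                    mean_exposure = mean_exposure,
                    n = nb, cases = cases,
                    elogit = log((cases + 0.5) / (nb - cases + 0.5)))
  out <- out[order(out$mean_exposure), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binned_logit_curve", "data.frame")
  out
}

# Profile weighted SSE of the continuous broken-stick model at fixed cutpoint:
# g(x) = a + b1*x + (b2 - b1)*max(0, x - c).  Given c the model is linear in
# (a, b1, gamma), so the profile minimum is a weighted least-squares solve.
.segmented_profile <- function(x, ylog, w, c) {
  X <- cbind(1, x, pmax(0, x - c))
  fit <- stats::lm.wfit(X, ylog, w)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  sse <- sum(w * fit$residuals^2)
  list(sse = sse, a = cf[[1L]], b1 = cf[[2L]], b2 = cf[[2L]] + cf[[3L]])
}

#' Segmented (broken-stick) fit of a binned logit curve
#'
#' Estimates the inflection point and flanking slopes by minimizing the
#' bin-size-weighted sum of squared errors of the continuous broken-stick
#' model `g(x) = a + b1*x + (b2 - b1)*max(0, x - c)` over the binned
#' empirical-logit curve.  The cutpoint is profiled out: a coarse grid over
#' the interior bin means (restricted to the 5th-95th percentile of bin
#' means, to avoid boundary degeneracy) is followed by local golden-section
#' refinement between the neighbours of the best grid candidate.  Grid ties
#' are broken toward the smaller cutpoint.
#'
#' @param curve A [binned_logit()] curve (or any data frame with columns
#'   `mean_exposure`, `n`, `elogit`).
#' @param quantile_bounds Cutpoint search window as quantiles of the bin
#'   means; default `c(0.05, 0.95)`.
#' @return An object of class `segmented_fit`: list with `cutpoint`,
#'   `intercept`, `slope_below`, `slope_above`, `sse`, `sse_line` (best
#'   single-line fit), `converged`, `iterations`.
#' @export
fit_segmented <- function(curve, quantile_bounds = c(0.05, 0.95)) {
  x <- curve$mean_exposure; ylog <- curve$elogit; w <- as.numeric(curve$n)
  keep <- is.finite(x) & is.finite(ylog) & is.finite(w) & w > 0
  x <- x[keep]; ylog <- ylog[keep]; w <- w[keep]
  if (length(x) < 10L) stop("need at least 10 bins for a segmented fit")
  if (diff(range(x)) == 0) stop("all bin exposures identical")
  o <- order(x); x <- x[o]; ylog <- ylog[o]; w <- w[o]

  qb <- stats::quantile(x, probs = quantile_bounds, type = 7, names = FALSE)
  grid <- x[x >= qb[1L] & x <= qb[2L]]
  grid <- grid[grid > x[1L] & grid < x[length(x)]]
  if (length(grid) == 0L) grid <- stats::median(x)

  sses <- vapply(grid, function(c) .segmented_profile(x, ylog, w, c)$sse, 0)
  best_i <- which(sses <= min(sses) + 0)[1L]  # first minimum = smallest cutpoint
  c_best <- grid[best_i]
  iterations <- length(grid)
  converged <- TRUE

  # local refinement between the neighbouring grid candidates
  lo <- if (best_i > 1L) grid[best_i - 1L] else max(x[1L], c_best - diff(range(x)) / 100)
  hi <- if (best_i < length(grid)) grid[best_i + 1L] else min(x[length(x)], c_best + diff(range(x)) / 100)
  if (hi > lo) {
    opt <- stats::optimize(function(c) .segmented_profile(x, ylog, w, c)$sse,
                           interval = c(lo, hi), tol = 1e-8)
    iterations <- iterations + 1L
    if (opt$objective <= sses[best_i] + 1e-12) c_best <- opt$minimum
  }
  prof <- .segmented_profile(x, ylog, w, c_best)
  line <- stats::lm.wfit(cbind(1, x), ylog, w)
  sse_line <- sum(w * line$residuals^2)
  if (prof$sse > sse_line + 1e-10) converged <- FALSE

  structure(list(cutpoint = c_best, intercept = prof$a,
                 slope_below = prof$b1, slope_above = prof$b2,
                 sse = prof$sse, sse_line = sse_line,
                 converged = converged, iterations = iterations),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "<segmented_fit> cutpoint %.4g; slopes %.4g (below) / %.4g (above); wSSE %.4g%s\n",
    x$cutpoint, x$slope_below, x$slope_above, x$sse,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Observed and predicted logits for a segmented fit
#'
#' Convenience table for diagnostic plots: the binned curve together with the
#' broken-stick prediction at each bin mean.
#'
#' @param curve A [binned_logit()] curve.
#' @param fit A [fit_segmented()] result.
#' @return Data frame with `mean_exposure`, `n`, `observed`, `predicted`.
#' @export
segmented_curve_table <- function(curve, fit) {
  pred <- fit$intercept + fit$slope_below * curve$mean_exposure +
    (fit$slope_above - fit$slope_below) * pmax(0, curve$mean_exposure - fit$cutpoint)
  data.frame(mean_exposure = curve$mean_exposure, n = curve$n,
             observed = curve$elogit, predicted = pred)
}
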