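# Exposure-encoding families ("link functions") as design-matrix columns.
# "Link function" here follows the epidemiological usage: the functional form
# encoding a pollutant concentration inside the logistic linear predictor,
# not the GLM logit link (which is always logit).

#' Create a link-function specification
#'
#' A `link_spec` describes how one pollutant's concentration enters the
#' logistic linear predictor: as-is (`"linear"`), as a hinge above a cutpoint
#' (`"threshold"`), as two segments with a possible level shift
#' (`"interaction"`), or as a restricted cubic spline (`"rcs"`).
#'
#' @param pollutant Character name of the pollutant the spec applies to.
#' @param kind One of `"linear"`, `"threshold"`, `"interaction"`, `"rcs"`.
#' @param cutpoint Inflection point in ug/m3; required for `"threshold"` and
#'   `"interaction"`.
#' @param knots Strictly increasing knot locations in ug/m3 (3 to 7 knots);
#'   required for `"rcs"`.
#' @return An object of class `link_spec`.
#' @export
link_spec <- function(pollutant, kind, cutpoint = NULL, knots = NULL) {
  kind <- match.arg(kind, c("linear", "threshold", "interaction", "rcs"))
  if (kind %in% c("threshold", "interaction")) {
    if (is.null(cutpoint) || !is.finite(cutpoint)) {
      stop("kind '", kind, "' requires a finite cutpoint")
    }
    knots <- NULL
  } else if (kind == "rcs") {
    if (is.null(knots)) stop("kind 'rcs' requires knots")
    k <- length(knots)
    if (k < 3L || k > 7L) stop("rcs requires between 3 and 7 knots")
    if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
    cutpoint <- NULL
  } else {
    cutpoint <- NULL
    knots <- NULL
  }
  structure(list(pollutant = pollutant, kind = kind,
                 cutpoint = cutpoint, knots = unname(knots)),
            class = "link_spec")
}

#' @export
print.link_spec <- function(x, ...) {
  extra <- switch(x$kind,
    threshold = ,
    interaction = sprintf(" (cutpoint %.4g)", x$cutpoint),
    rcs = sprintf(" (%d knots: %s)", length(x$knots),
                  paste(signif(x$knots, 4), collapse = ", ")),
    "")
  cat(sprintf("<link_spec> %s: %s%s\n", x$pollutant, x$kind, extra))
  invisible(x)
}

#' Linear basis
#'
#' Identity encoding: one column equal to the exposure itself.
#'
#' @param x Numeric exposure vector.
#' @return A one-column numeric matrix.
#' @export
linear_basis <- function(x) {
  matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, "x"))
}

#' Threshold (hinge) basis
#'
#' Encodes a flat baseline below the cutpoint and a unit slope above it:
#' `max(0, x - cutpoint)`.  The boundary value `x == cutpoint` belongs to the
#' baseline side (column value 0).
#'
#' @param x Numeric exposure vector.
#' @param cutpoint Inflection point in the same units as `x`.
#' @return A one-column numeric matrix.
#' @export
threshold_basis <- function(x, cutpoint) {
  stopifnot(is.finite(cutpoint))
  matrix(pmax(0, as.numeric(x) - cutpoint), ncol = 1L,
         dimnames = list(NULL, "hinge"))
}

#' Interaction (two-segment) basis
#'
#' Three columns: the exposure, an above-cutpoint indicator `1{x >= c}`, and
#' their product.  Together with the intercept these allow different slopes
#' below and above the cutpoint plus a discontinuity at the cutpoint.  The
#' spanned space contains the threshold basis (hinge = x*d - c*d).
#'
#' @inheritParams threshold_basis
#' @return A three-column numeric matrix.
#' @export
interaction_basis <- function(x, cutpoint) {
  stopifnot(is.finite(cutpoint))
  x <- as.numeric(x)
  d <- as.numeric(x >= cutpoint)
  cbind(x = x, above = d, x_above = x * d)
}

#' Restricted cubic spline basis
#'
#' Harrell-form restricted cubic spline: `k` knots yield `k - 1` columns.
#' Column 1 is `x`; columns `j = 2 .. k-1` are restricted truncated-cubic
#' terms scaled by `(t_k - t_1)^2` so that the spanned function is cubic
#' between knots, has continuous value, first and second derivatives, and is
#' linear outside `[t_1, t_k]`.
#'
#' @param x Numeric exposure vector.
#' @param knots Strictly increasing numeric vector of 3 to 7 knot locations.
#' @return A numeric matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3L || k > 7L) stop("rcs requires between 3 and 7 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing (no duplicates)")
  x <- as.numeric(x)
  norm <- (knots[k] - knots[1L])^2
  cube <- function(u) pmax(0, u)^3
  out <- matrix(0, nrow = length(x), ncol = k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]; tk1 <- knots[k - 1L]; tk <- knots[k]
    out[, j + 1L] <- (cube(x - tj) -
                      cube(x - tk1) * (tk - tj) / (tk - tk1) +
                      cube(x - tk)  * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("rcs", seq_len(k - 2L)))
  out
}

#' First derivative of the restricted cubic spline basis
#'
#' Derivative of each `rcs_basis()` column with respect to `x`; used to
#' compute per-unit slopes of fitted spline curves.
#'
#' @inheritParams rcs_basis
#' @return A numeric matrix, same shape as `rcs_basis(x, knots)`.
#' @export
rcs_basis_deriv <- function(x, knots) {
  k <- length(knots)
  if (k < 3L || k > 7L) stop("rcs requires between 3 and 7 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  x <- as.numeric(x)
  norm <- (knots[k] - knots[1L])^2
  sq <- function(u) pmax(0, u)^2
  out <- matrix(0, nrow = length(x), ncol = k - 1L)
  out[, 1L] <- 1
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]; tk1 <- knots[k - 1L]; tk <- knots[k]
    out[, j + 1L] <- 3 * (sq(x - tj) -
                          sq(x - tk1) * (tk - tj) / (tk - tk1) +
                          sq(x - tk)  * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("rcs", seq_len(k - 2L)))
  out
}

#' Build the design columns for a link specification
#'
#' @param x Numeric exposure vector.
#' @param spec A [link_spec()].
#' @return Numeric matrix of basis columns (no intercept).
#' @export
basis_matrix <- function(x, spec) {
  stopifnot(inherits(spec, "link_spec"))
  switch(spec$kind,
    linear      = linear_basis(x),
    threshold   = threshold_basis(x, spec$cutpoint),
    interaction = interaction_basis(x, spec$cutpoint),
    rcs         = rcs_basis(x, spec$knots))
}

#' Number of design columns a link specification produces
#' @param spec A [link_spec()].
#' @return Integer column count.
#' @export
basis_width <- function(spec) {
  switch(spec$kind,
    linear = 1L, threshold = 1L, interaction = 3L,
    rcs = length(spec$knots) - 1L)
}

# Quantile tables for default knot placement (standard recommendation).
.knot_quantiles <- list(
  `3` = c(.10, .50, .90),
  `4` = c(.05, .35, .65, .95),
  `5` = c(.05, .275, .50, .725, .95),
  `6` = c(.05, .23, .41, .59, .77, .95),
  `7` = c(.025, .1833, .3417, .50, .6583, .8167, .975)
)

#' Default knot locations for a restricted cubic spline
#'
#' Places `k` knots at the conventional quantiles of the observed exposure
#' sample (for example, at the 10th/50th/90th percentiles when `k = 3`).
#'
#' @param x_sample Numeric sample of exposures (length at least `10 * k`).
#' @param k Number of knots, 3 to 7.
#' @return Numeric vector of `k` strictly increasing knot locations.
#' @export
default_knots <- function(x_sample, k) {
  k <- as.integer(k)
  if (k < 3L || k > 7L) stop("k must be between 3 and 7")
  x_sample <- x_sample[is.finite(x_sample)]
  if (length(x_sample) < 10L * k) {
    stop("need at least ", 10L * k, " observations to place ", k, " knots")
  }
  kn <- unname(stats::quantile(x_sample, probs = .knot_quantiles[[as.character(k)]],
                               type = 7, names = FALSE))
  if (any(diff(kn) <= 0)) {
    stop("degenerate sample: ties make knot locations coincide")
  }
  kn
}
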