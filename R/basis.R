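#' One-dimensional spline basis specification
#'
#' A `basis_spec` describes one margin of a DLNM cross-basis: either the
#' exposure-response function (temperature or ARI incidence) or the
#' lag-response function.  Supported families are the quadratic B-spline
#' used for temperature, the natural cubic spline used for ARI incidence,
#' lag-response functions and the long-term trend, and degenerate linear /
#' constant bases used mainly for toy models and cross-checks.
#'
#' Column counts follow the usual spline dimension rules: a quadratic
#' B-spline with `m` interior knots spans `m + 3` columns with an intercept
#' and `m + 2` without; a natural cubic spline with `m` interior knots spans
#' `m + 2` with an intercept and `m + 1` without.
#'
#' @param family One of `"quadratic-bspline"`, `"natural-cubic"`,
#'   `"linear"`, `"constant"`.
#' @param interior_knots Strictly increasing numeric vector of interior
#'   knots, strictly inside the boundary interval.  Ignored for the linear
#'   and constant families.
#' @param boundary_knots Length-2 numeric vector `c(lo, hi)` with `lo < hi`.
#' @param intercept Should the basis span the constant function?
#'
#' @return An object of class `basis_spec`.
#' @seealso [eval_basis()], [cross_basis()]
#' @export
basis_spec <- function(family = c("natural-cubic", "quadratic-bspline",
                                  "linear", "constant"),
                       interior_knots = numeric(),
                       boundary_knots = NULL,
                       intercept = FALSE) {
  family <- match.arg(family)
  interior_knots <- as.numeric(interior_knots)
  if (family %in% c("linear", "constant")) {
    interior_knots <- numeric()
  } else {
    if (is.null(boundary_knots)) {
      stop("`boundary_knots` must be supplied for spline families")
    }
  }
  if (!is.null(boundary_knots)) {
    boundary_knots <- as.numeric(boundary_knots)
    if (length(boundary_knots) != 2L || !all(is.finite(boundary_knots)) ||
        boundary_knots[1] >= boundary_knots[2]) {
      stop("`boundary_knots` must be c(lo, hi) with lo < hi")
    }
    if (length(interior_knots) &&
        (any(interior_knots <= boundary_knots[1]) ||
         any(interior_knots >= boundary_knots[2]))) {
      stop("interior knots must lie strictly inside the boundary interval")
    }
  }
  if (length(interior_knots) && any(diff(interior_knots) <= 0)) {
    stop("interior knots must be strictly increasing")
  }
  structure(
    list(family = family, interior_knots = interior_knots,
         boundary_knots = boundary_knots, intercept = isTRUE(intercept)),
    class = "basis_spec"
  )
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("<basis_spec> ", x$family,
      " | interior knots: ", paste(signif(x$interior_knots, 4), collapse = ", "),
      " | boundary: [", paste(signif(x$boundary_knots, 4), collapse = ", "),
      "] | intercept: ", x$intercept, "\n", sep = "")
  invisible(x)
}

#' Number of columns a basis specification evaluates to
#'
#' @param spec A [basis_spec()].
#' @return Integer column count.
#' @export
basis_dim <- function(spec) {
  m <- length(spec$interior_knots)
  ic <- as.integer(spec$intercept)
  switch(spec$family,
    "quadratic-bspline" = m + 2L + ic,
    "natural-cubic"     = m + 1L + ic,
    "linear"            = 1L + ic,
    "constant"          = 1L
  )
}

#' Place knots at empirical percentiles
#'
#' Knot rule used for the temperature exposure-response spline: interior
#' knots at given percentiles of the observed daily mean temperature
#' distribution (default practice places them at the 10th, 75th and 90th).
#' Percentiles are computed with linear interpolation between order
#' statistics (`stats::quantile()` type 7).
#'
#' @param values Numeric vector of observed values.
#' @param percentiles Strictly increasing percentile levels in (0, 100).
#' @return Strictly increasing knot vector; collisions raise an error
#'   naming the colliding percentiles.
#' @export
place_percentile_knots <- function(values, percentiles = c(10, 75, 90)) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("`values` must contain finite entries")
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0) ||
      any(percentiles >= 100)) {
    stop("`percentiles` must be strictly increasing within (0, 100)")
  }
  k <- unname(stats::quantile(values, probs = percentiles / 100,
                              type = 7, names = FALSE))
  if (any(diff(k) <= 0)) {
    dup <- which(diff(k) <= 0)[1]
    stop(sprintf(
      "degenerate knots: percentiles %g and %g both map to %g",
      percentiles[dup], percentiles[dup + 1], k[dup]))
  }
  k
}

#' Place equally spaced interior knots over a range
#'
#' Knot rule used for the ARI exposure-response spline: `n_knots` interior
#' knots splitting `[lo, hi]` into `n_knots + 1` equal segments.
#'
#' @param lo,hi Range endpoints, `lo < hi`.
#' @param n_knots Number of interior knots (>= 1).
#' @return Knot vector `lo + i * (hi - lo) / (n_knots + 1)`, i = 1..n_knots.
#' @export
place_equispaced_knots <- function(lo, hi, n_knots) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) stop("need lo < hi")
  if (n_knots < 1) stop("`n_knots` must be >= 1")
  lo + seq_len(n_knots) * (hi - lo) / (n_knots + 1)
}

#' Place lag knots equally spaced on the log scale
#'
#' Knot rule for the lag-response spline over lags 0..`lag_max`: knots at
#' `exp(i * log(lag_max) / (n_knots + 1))`, i.e. equally spaced in log-lag
#' between lag 1 and `lag_max` with the endpoints excluded.  Lag 0 cannot
#' anchor a log-scale grid, so lag 1 is the conventional base point.
#'
#' @param lag_max Maximum lag in days (>= 2).
#' @param n_knots Number of interior knots (>= 1).
#' @return Knot vector on the lag scale.
#' @export
log_spaced_lag_knots <- function(lag_max, n_knots) {
  if (lag_max < 2) stop("`lag_max` must be >= 2")
  if (n_knots < 1) stop("`n_knots` must be >= 1")
  exp(seq_len(n_knots) * log(lag_max) / (n_knots + 1))
}

#' Evaluate a spline basis
#'
#' Evaluates the basis described by a [basis_spec()] at `x`.  Quadratic
#' B-splines use the Cox-de Boor construction via [splines::bs()]; natural
#' cubic splines use [splines::ns()], whose basis has zero second derivative
#' at the boundary knots and extrapolates linearly beyond them.  Values
#' outside the boundary interval are extrapolated, never clipped: the ARI
#' reference of zero incidence lies below any observed minimum, so linear
#' extrapolation of the natural spline is part of the contract.
#'
#' @param spec A [basis_spec()].
#' @param x Numeric vector (finite).
#' @return Numeric matrix `length(x)` by [basis_dim()].
#' @export
eval_basis <- function(spec, x) {
  stopifnot(inherits(spec, "basis_spec"))
  if (any(!is.finite(x))) stop("`x` must be finite")
  out <- switch(spec$family,
    "quadratic-bspline" = suppressWarnings(splines::bs(
      x, knots = spec$interior_knots, degree = 2L,
      intercept = spec$intercept, Boundary.knots = spec$boundary_knots)),
    "natural-cubic" = splines::ns(
      x, knots = if (length(spec$interior_knots)) spec$interior_knots,
      intercept = spec$intercept, Boundary.knots = spec$boundary_knots),
    "linear" = if (spec$intercept) cbind(1, x) else matrix(x, ncol = 1L),
    "constant" = matrix(1, nrow = length(x), ncol = 1L)
  )
  out <- unname(as.matrix(out))
  dimnames(out) <- list(NULL, paste0("b", seq_len(ncol(out))))
  out
}
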