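#' Cross-basis specification
#'
#' Pairs an exposure-response [basis_spec()] with a lag-response
#' [basis_spec()] over lags `0..lag_max`.  Following the usual DLNM
#' identifiability convention the exposure basis is built without its
#' intercept (the model intercept absorbs it) while the lag basis keeps an
#' intercept so lag-uniform effects are representable.
#'
#' @param var_spec [basis_spec()] for the exposure dimension.
#' @param lag_spec [basis_spec()] for the lag dimension; its boundary knots
#'   must be `c(0, lag_max)`.
#' @param lag_max Maximum lag in days (default 21).
#' @return An object of class `cross_basis_spec`.
#' @export
cross_basis_spec <- function(var_spec, lag_spec, lag_max = 21L) {
  stopifnot(inherits(var_spec, "basis_spec"), inherits(lag_spec, "basis_spec"))
  lag_max <- as.integer(lag_max)
  if (lag_max < 0L) stop("`lag_max` must be >= 0")
  if (!is.null(lag_spec$boundary_knots) &&
      !isTRUE(all.equal(lag_spec$boundary_knots, c(0, lag_max)))) {
    stop("lag basis boundary knots must be c(0, lag_max)")
  }
  structure(list(var_spec = var_spec, lag_spec = lag_spec, lag_max = lag_max),
            class = "cross_basis_spec")
}

#' Default temperature cross-basis specification
#'
#' Quadratic B-spline exposure-response with interior knots at the 10th,
#' 75th and 90th percentiles of the observed series (5 columns), and a
#' natural cubic lag-response with two interior knots equally spaced in
#' log-lag over 0--21 days (4 columns, intercept included): 20 cross-basis
#' columns in total.
#'
#' @param x Observed daily mean temperature series.
#' @param knot_percentiles Percentiles for the exposure knots.
#' @param lag_max Maximum lag (days).
#' @param n_lag_knots Interior lag knots, log-spaced.
#' @return A [cross_basis_spec()].
#' @export
temperature_cb_spec <- function(x, knot_percentiles = c(10, 75, 90),
                                lag_max = 21L, n_lag_knots = 2L) {
  var_spec <- basis_spec("quadratic-bspline",
                         interior_knots = place_percentile_knots(x, knot_percentiles),
                         boundary_knots = range(x), intercept = FALSE)
  lag_spec <- basis_spec("natural-cubic",
                         interior_knots = log_spaced_lag_knots(lag_max, n_lag_knots),
                         boundary_knots = c(0, lag_max), intercept = TRUE)
  cross_basis_spec(var_spec, lag_spec, lag_max)
}

#' Default ARI cross-basis specification
#'
#' Natural cubic exposure-response with 4 interior knots (5 columns) and a
#' natural cubic lag-response with a single interior knot over 0--21 days
#' (3 columns, intercept included): 15 cross-basis columns.  Exposure knots
#' are equally spaced over the observed incidence range by default;
#' `knot_style = "percentile"` places them at equally spaced percentiles
#' instead.  The lower boundary knot stays at the observed minimum; the
#' reference of zero incidence is reached by the natural spline's linear
#' extrapolation.
#'
#' @param x Observed daily ARI incidence series (cases per 100,000).
#' @param n_knots Interior exposure knots.
#' @param lag_max Maximum lag (days).
#' @param n_lag_knots Interior lag knots (equally spaced over the lag range).
#' @param knot_style `"range"` (default) or `"percentile"`.
#' @return A [cross_basis_spec()].
#' @export
ari_cb_spec <- function(x, n_knots = 4L, lag_max = 21L, n_lag_knots = 1L,
                        knot_style = c("range", "percentile")) {
  knot_style <- match.arg(knot_style)
  knots <- switch(knot_style,
    range = place_equispaced_knots(min(x), max(x), n_knots),
    percentile = place_percentile_knots(
      x, seq_len(n_knots) * 100 / (n_knots + 1)))
  var_spec <- basis_spec("natural-cubic", interior_knots = knots,
                         boundary_knots = range(x), intercept = FALSE)
  lag_spec <- basis_spec("natural-cubic",
                         interior_knots = place_equispaced_knots(0, lag_max, n_lag_knots),
                         boundary_knots = c(0, lag_max), intercept = TRUE)
  cross_basis_spec(var_spec, lag_spec, lag_max)
}

#' Matrix of lagged exposures
#'
#' Entry `(t, l + 1)` holds the exposure `l` days before day `t`
#' (`x[t - l]`); entries reaching before the start of the series are `NA`.
#'
#' @param x Numeric exposure series of length `n > lag_max`.
#' @param lag_max Maximum lag.
#' @return `n` by `lag_max + 1` matrix with columns `lag0..lag<lag_max>`.
#' @export
lag_matrix <- function(x, lag_max) {
  n <- length(x)
  lag_max <- as.integer(lag_max)
  if (n <= lag_max) stop("series must be longer than `lag_max`")
  out <- vapply(0:lag_max, function(l) c(rep(NA_real_, l), x[seq_len(n - l)]),
                numeric(n))
  colnames(out) <- paste0("lag", 0:lag_max)
  out
}

#' Build a DLNM cross-basis matrix
#'
#' Computes the `n` by `J * K` design block whose column `(j, k)` at day `t`
#' is `sum_l a_j(x[t - l]) * c_k(l)`, where `a_j` are the exposure basis
#' functions and `c_k` the lag basis functions evaluated at integer lags
#' `0..lag_max`.  The first `lag_max` rows have incomplete exposure history
#' and are returned as `NA`; model fitting drops them rather than imputing
#' pre-study exposure.
#'
#' Columns are ordered with the lag index fastest: column `(j - 1) * K + k`.
#'
#' @param x Numeric exposure series.
#' @param spec A [cross_basis_spec()].
#' @return A `cross_basis` object: the numeric matrix with attributes
#'   `spec` (the specification) and `x` (the raw series).
#' @export
cross_basis <- function(x, spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  if (any(!is.finite(x))) stop("exposure series must be finite")
  n <- length(x)
  L <- spec$lag_max
  Q <- lag_matrix(x, L)
  C <- eval_basis(spec$lag_spec, 0:L)              # (L+1) x K
  J <- basis_dim(spec$var_spec)
  K <- ncol(C)
  cb <- matrix(NA_real_, n, J * K)
  ok <- seq.int(L + 1L, n)
  # evaluate exposure basis on all lagged values of complete rows at once
  A <- eval_basis(spec$var_spec, as.vector(Q[ok, , drop = FALSE]))  # (nok*(L+1)) x J
  nok <- length(ok)
  for (j in seq_len(J)) {
    Aj <- matrix(A[, j], nrow = nok, ncol = L + 1L)
    cb[ok, (j - 1L) * K + seq_len(K)] <- Aj %*% C
  }
  colnames(cb) <- as.vector(t(outer(seq_len(J), seq_len(K),
                                    function(j, k) paste0("v", j, ".l", k))))
  structure(cb, spec = spec, x = x, class = c("cross_basis", "matrix", "array"))
}

#' Column index of cross-basis column (j, k)
#'
#' @param spec A [cross_basis_spec()].
#' @param j Exposure-basis index (1..J).
#' @param k Lag-basis index (1..K).
#' @return Integer column index into the cross-basis matrix.
#' @export
cb_column_index <- function(spec, j, k) {
  K <- basis_dim(spec$lag_spec)
  J <- basis_dim(spec$var_spec)
  stopifnot(all(j >= 1 & j <= J), all(k >= 1 & k <= K))
  (j - 1L) * K + k
}

#' Cumulative lag weights
#'
#' The vector `w_k = sum_{l=0}^{L} c_k(l)` that reduces the exposure-lag
#' surface to the overall cumulative association: the cumulative log
#' relative risk at exposure `x` versus centre `x0` is
#' `sum_{j,k} eta_jk * (a_j(x) - a_j(x0)) * w_k`.
#'
#' @param lag_spec [basis_spec()] for the lag dimension.
#' @param lag_max Maximum lag.
#' @return Numeric vector of length K.
#' @export
cumulative_lag_weights <- function(lag_spec, lag_max) {
  unname(colSums(eval_basis(lag_spec, 0:lag_max)))
}
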