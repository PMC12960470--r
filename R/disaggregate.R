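#' Disaggregate weekly totals into a smooth daily series
#'
#' Converts weekly ARI incidence totals into daily values that preserve
#' each weekly total exactly while joining fluently across week
#' boundaries.  The cumulative weekly totals are interpolated at the week
#' boundaries with a monotone (Hyman-filtered) cubic spline and differenced
#' into daily values; monotonicity of the cumulative interpolant keeps the
#' daily values non-negative, and any residual negatives are clipped to
#' zero with a per-week multiplicative rescale so the weekly sums are exact
#' to 1e-9.
#'
#' @param weekly Data frame with columns `week_start` (`Date`, consecutive
#'   Mondays or any fixed weekday at 7-day spacing) and `incidence`
#'   (non-negative weekly totals).  At least 3 weeks.
#' @return Tibble with columns `date` and `incidence` (one row per day,
#'   7 per input week).
#' @seealso [smooth_14day()], [disaggregate_ari()]
#' @export
weekly_to_daily <- function(weekly) {
  stopifnot(all(c("week_start", "incidence") %in% names(weekly)),
            inherits(weekly$week_start, "Date"))
  v <- weekly$incidence
  if (nrow(weekly) < 3) stop("need at least 3 weeks")
  if (any(v < 0)) stop("weekly totals must be non-negative")
  if (any(diff(as.integer(weekly$week_start)) != 7L)) {
    stop("`week_start` must advance in exact 7-day steps")
  }
  W <- length(v)
  cum <- c(0, cumsum(v))
  f <- stats::splinefun(seq(0, 7 * W, by = 7), cum, method = "hyman")
  daily <- diff(f(0:(7 * W)))
  daily[daily < 0] <- 0
  # exact per-week totals (guards rounding; hyman already hits the knots)
  wk <- rep(seq_len(W), each = 7)
  sums <- tapply(daily, wk, sum)
  scale <- ifelse(sums > 0, v / sums, 0)
  daily <- daily * scale[wk]
  tibble::tibble(
    date = weekly$week_start[1] + 0:(7 * W - 1),
    incidence = as.numeric(daily)
  )
}

#' Locally weighted 14-day smoother
#'
#' Local linear regression with tricube weights over a centred 14-day
#' window (half-width 7 days, shrunk near the series ends).  Reproduces
#' constants and straight lines exactly and never overshoots a single
#' spike; applied to the disaggregated daily ARI series, after which the
#' weekly totals are preserved only approximately.
#'
#' @param x Numeric vector (length >= 14).
#' @param half_width Window half-width in days (default 7, i.e. a 14-day
#'   smoothing window).
#' @return Smoothed vector of the same length.
#' @export
smooth_14day <- function(x, half_width = 7L) {
  n <- length(x)
  if (n < 2 * half_width) stop("series shorter than the smoothing window")
  out <- numeric(n)
  t0 <- seq_len(n)
  for (i in t0) {
    lo <- max(1L, i - half_width); hi <- min(n, i + half_width)
    d <- (lo:hi) - i
    h <- max(abs(d)) + 1
    w <- (1 - (abs(d) / h)^3)^3
    # weighted least squares line through the window, evaluated at d = 0
    sw <- sum(w); swd <- sum(w * d); swd2 <- sum(w * d^2)
    swy <- sum(w * x[lo:hi]); swdy <- sum(w * d * x[lo:hi])
    den <- sw * swd2 - swd^2
    out[i] <- if (den > 0) (swd2 * swy - swd * swdy) / den else swy / sw
  }
  out
}

#' Weekly ARI surveillance to a smooth daily incidence series
#'
#' Convenience wrapper chaining [weekly_to_daily()] (total-preserving
#' decomposition) and [smooth_14day()] (14-day locally weighted
#' regression), mirroring how weekly ARI surveillance reports are prepared
#' for daily time-series regression.
#'
#' @inheritParams weekly_to_daily
#' @return Tibble with columns `date`, `incidence_raw`,
#'   `incidence_smoothed`.
#' @export
disaggregate_ari <- function(weekly) {
  daily <- weekly_to_daily(weekly)
  daily |>
    dplyr::mutate(incidence_raw = .data$incidence,
                  incidence_smoothed = pmax(smooth_14day(.data$incidence), 0)) |>
    dplyr::select("date", "incidence_raw", "incidence_smoothed")
}
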