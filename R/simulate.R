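#' Ground-truth data-generating process for synthetic daily series
#'
#' Bundles the known quantities behind the synthetic generator: baseline
#' log-mortality, a slow linear trend and residual winter seasonality on
#' the log scale, day-of-week effects, a separable J-shaped
#' temperature-mortality surface `s_T(x, l) = f_T(x) g_T(l)` that is zero
#' at the true minimum mortality temperature, and a separable monotone
#' ARI-mortality surface `s_A(x, l) = slope * x * g_A(l)` that is zero at
#' zero incidence.  Lag profiles `g(.)` decay exponentially and are
#' normalised to sum to one over lags 0..21, so `f_T(x)` (resp.
#' `slope * x`) is exactly the true cumulative log RR.
#'
#' Defaults emulate the scale of a Central-European national mortality
#' register: mean deaths around 315/day, cold RR near 1.30 at the 1st
#' temperature percentile, a steeper heat slope, an ARI effect of a few
#' percent of deaths, and a true MMT of 18 degC.  The baseline applies at
#' the MMT reference; since most days are colder than the MMT the overall
#' mean sits about 10% above it, hence the default of log(284) to land the
#' realised mean near 315/day.
#'
#' @param baseline_log Log of the baseline daily death count at the
#'   reference exposures (MMT, zero ARI).
#' @param trend_slope Total log-mortality change across the simulated span.
#' @param seasonal_amplitude Amplitude (log scale) of residual winter-peaked
#'   seasonality not mediated by temperature or ARI.
#' @param dow_effects Length-7 log-scale effects (Mon..Sun).
#' @param mmt True minimum mortality temperature (degC).
#' @param cold_coef,heat_coef Quadratic curvature of the cumulative log RR
#'   below/above the MMT; the heat limb is quadratic throughout,
#'   `heat_coef * (x - mmt)^2`.
#' @param cold_linear_below Width (degC) of the quadratic part of the cold
#'   limb; beyond `mmt - cold_linear_below` the limb continues linearly
#'   with matched slope, keeping cold RRs on the scale seen in national
#'   mortality series while the minimum stays sharply identified.
#' @param lag_scale_temp,lag_scale_ari e-folding scale (days) of the lag
#'   profiles.
#' @param ari_slope True cumulative log RR per unit ARI incidence.
#' @param ari_coupling Cold-to-ARI coupling: extra daily incidence per
#'   degree-day of recent cold load (see [simulate_daily_series()]);
#'   setting it (and/or `ari_slope`) to zero switches mediation off.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(baseline_log = log(284),
                             trend_slope = -0.10,
                             seasonal_amplitude = 0.03,
                             dow_effects = c(0, 0.005, 0.005, 0, 0,
                                             -0.01, -0.015),
                             mmt = 18,
                             cold_coef = 4e-3,
                             heat_coef = 4e-3,
                             cold_linear_below = 3,
                             lag_scale_temp = 5,
                             lag_scale_ari = 3,
                             ari_slope = 3.3e-4,
                             ari_coupling = 14) {
  stopifnot(length(dow_effects) == 7)
  structure(
    list(baseline_log = baseline_log, trend_slope = trend_slope,
         seasonal_amplitude = seasonal_amplitude, dow_effects = dow_effects,
         mmt = mmt, cold_coef = cold_coef, heat_coef = heat_coef,
         cold_linear_below = cold_linear_below,
         lag_scale_temp = lag_scale_temp, lag_scale_ari = lag_scale_ari,
         ari_slope = ari_slope, ari_coupling = ari_coupling),
    class = "simulation_truth"
  )
}

# true cumulative log RR of temperature vs the true MMT: quadratic in a
# neighbourhood of the minimum (C2 there, so the minimum is sharply
# identified), with the cold limb continuing linearly (C1) below
# mmt - cold_linear_below so cold RRs stay on a realistic scale
true_temp_curve_cold <- function(truth, x) {
  u <- truth$mmt - x
  d <- truth$cold_linear_below
  ifelse(u <= 0, 0,
         ifelse(u <= d, truth$cold_coef * u^2,
                truth$cold_coef * d^2 + 2 * truth$cold_coef * d * (u - d)))
}
true_temp_curve_heat <- function(truth, x) {
  ifelse(x > truth$mmt, truth$heat_coef * (x - truth$mmt)^2, 0)
}
true_temp_curve <- function(truth, x) {
  true_temp_curve_cold(truth, x) + true_temp_curve_heat(truth, x)
}

# true cumulative log RR of ARI vs zero incidence
true_ari_curve <- function(truth, x) truth$ari_slope * x

# normalised exponential lag profile over lags 0..lag_max
lag_profile <- function(scale, lag_max = 21L) {
  g <- exp(-(0:lag_max) / scale)
  g / sum(g)
}

#' Simulate a daily mean temperature series
#'
#' Annual sinusoid peaking in mid-July plus stationary AR(1) noise
#' (innovations scaled so `sd` is the marginal noise standard deviation).
#' Defaults emulate a Central-European series with mean 8.3 degC and an
#' observed range of roughly -15 to +28 degC.
#'
#' @param n_years Number of simulated years.
#' @param mean Long-run mean temperature (degC).
#' @param amplitude Seasonal amplitude (degC).
#' @param ar1 AR(1) coefficient of the noise.
#' @param sd Marginal standard deviation of the noise (degC).
#' @param start_year First calendar year of the series.
#' @param seed Optional integer seed.
#' @return Tibble with columns `date`, `tmean`.
#' @export
simulate_temperature <- function(n_years, mean = 8.3, amplitude = 10,
                                 ar1 = 0.8, sd = 3, start_year = 2000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- sim_dates(n_years, start_year)
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- mean + amplitude * cos(2 * pi * (doy - 196) / 365.25)
  noise <- if (sd > 0) {
    as.numeric(stats::arima.sim(list(ar = ar1), n,
                                sd = sd * sqrt(1 - ar1^2)))
  } else rep(0, n)
  tibble::tibble(date = dates, tmean = seasonal + noise)
}

#' Simulate a daily ARI incidence series
#'
#' Constant baseline endemic incidence plus one Gaussian-shaped winter
#' epidemic per season with log-normally distributed amplitude (so
#' occasional large seasons approach the upper few hundreds per 100,000)
#' and randomly timed peak centred on mid-January, small multiplicative
#' reporting noise, and a hard floor of 30 cases per 100,000.
#'
#' @param n_years Number of simulated years.
#' @param baseline Endemic incidence (cases per 100,000 per day).
#' @param epidemic_peak_mean Typical seasonal peak incidence (baseline plus
#'   median epidemic amplitude).
#' @param peak_sdlog Log-sd of the epidemic amplitude distribution.
#' @param peak_width_days Approximate full width of the epidemic bump.
#' @param floor Lower clip (cases per 100,000).
#' @param start_year First calendar year.
#' @param seed Optional integer seed.
#' @return Tibble with columns `date`, `ari`.
#' @export
simulate_ari <- function(n_years, baseline = 90, epidemic_peak_mean = 260,
                         peak_sdlog = 0.5, peak_width_days = 35,
                         floor = 30, start_year = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- sim_dates(n_years, start_year)
  n <- length(dates)
  day <- as.integer(dates - dates[1]) + 1L
  x <- rep(baseline, n)
  amp_med <- max(epidemic_peak_mean - baseline, 0)
  width_sd <- peak_width_days / 2.355          # FWHM -> Gaussian sd
  # seasons are centred on Jan 15 of each simulated year (plus the one
  # preceding the series so the first winter has a left shoulder)
  for (y in seq(start_year - 1L, start_year + n_years)) {
    centre <- as.integer(as.Date(sprintf("%d-01-15", y)) - dates[1]) + 1L +
      round(stats::rnorm(1, 0, 15))
    amp <- if (amp_med > 0) stats::rlnorm(1, log(amp_med), peak_sdlog) else 0
    x <- x + amp * exp(-(day - centre)^2 / (2 * width_sd^2))
  }
  x <- x * exp(stats::rnorm(n, 0, 0.05))
  tibble::tibble(date = dates, ari = pmax(x, floor))
}

#' Simulate daily death counts from known surfaces
#'
#' Draws `deaths[t] ~ Poisson(exp(eta_t))` with
#' `eta_t = baseline + trend + seasonality + dow +
#'  sum_l s_T(tmean[t-l], l) + sum_l s_A(ari[t-l], l)`.
#' The first 21 days lack full exposure history; their missing lags are
#' padded by replicating the first observed day.  With `overdispersion > 1`
#' a gamma frailty multiplies the rate so the counts are quasi-Poisson with
#' that known dispersion.
#'
#' @param tmean,ari Aligned daily exposure series.
#' @param dates Aligned `Date` vector.
#' @param truth A [simulation_truth()].
#' @param overdispersion Target variance-to-mean ratio (default 1, pure
#'   Poisson).
#' @param seed Optional integer seed.
#' @return Integer vector of daily death counts.
#' @export
simulate_mortality <- function(tmean, ari, dates, truth = simulation_truth(),
                               overdispersion = 1, seed = NULL) {
  stopifnot(length(tmean) == length(ari), length(dates) == length(tmean),
            length(tmean) > 21)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tmean)
  doy <- as.integer(format(dates, "%j"))
  dowi <- as.integer(format(dates, "%u"))
  eta <- truth$baseline_log +
    truth$trend_slope * (seq_len(n) - n / 2) / n +
    truth$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    truth$dow_effects[dowi] +
    true_cumulative_contribution(tmean, true_temp_curve(truth, tmean),
                                 lag_profile(truth$lag_scale_temp)) +
    true_cumulative_contribution(ari, true_ari_curve(truth, ari),
                                 lag_profile(truth$lag_scale_ari))
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  mu <- exp(eta)
  if (overdispersion > 1) {
    shape <- 1 / (overdispersion - 1) * mean(mu)   # Var = mu * overdispersion (approx at mean rate)
    mu <- mu * stats::rgamma(n, shape = shape, rate = shape)
  }
  stats::rpois(n, mu)
}

# sum_l f(x[t-l]) g(l) with pre-series history padded by day 1
true_cumulative_contribution <- function(x, fx, g) {
  L <- length(g) - 1L
  Q <- lag_matrix(fx, L)
  Q[is.na(Q)] <- fx[1]
  drop(Q %*% g)
}

#' Simulate a complete daily mortality study
#'
#' End-to-end generator: temperature, ARI incidence (with configurable
#' cold-to-ARI coupling so part of the cold effect on mortality is
#' genuinely mediated by ARIs), and Poisson death counts from the known
#' surfaces.  The coupling adds `ari_coupling` cases per 100,000 for every
#' degree-day of cold load, defined as the mean of
#' `max(0, 10 - tmean)` over the previous 14 days — epidemics intensify
#' after cold spells, which is the mediation pathway the paired-model
#' contrast is designed to recover.
#'
#' @param n_years Simulated span in years.
#' @param truth A [simulation_truth()].
#' @param start_year First calendar year.
#' @param overdispersion Variance-to-mean ratio of the counts.
#' @param seed Optional integer seed (one stream drives all three series).
#' @return Tibble with columns `date`, `deaths`, `tmean`, `ari`, `dow`,
#'   with the `truth` object attached as attribute `"truth"`.
#' @export
simulate_daily_series <- function(n_years = 10, truth = simulation_truth(),
                                  start_year = 2000, overdispersion = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tmp <- simulate_temperature(n_years, start_year = start_year)
  ari <- simulate_ari(n_years, start_year = start_year)$ari
  if (truth$ari_coupling > 0) {
    cold <- pmax(0, 10 - tmp$tmean)
    Q <- lag_matrix(cold, 14L)
    Q[is.na(Q)] <- cold[1]
    load <- rowMeans(Q[, -1, drop = FALSE])       # lags 1..14
    ari <- pmax(ari + truth$ari_coupling * load, 30)
  }
  deaths <- simulate_mortality(tmp$tmean, ari, tmp$date, truth,
                               overdispersion = overdispersion)
  out <- tibble::tibble(
    date = tmp$date, deaths = as.integer(deaths), tmean = tmp$tmean,
    ari = ari,
    dow = factor(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[
      as.integer(format(tmp$date, "%u"))],
      levels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")))
  attr(out, "truth") <- truth
  out
}

sim_dates <- function(n_years, start_year) {
  seq(as.Date(sprintf("%d-01-01", start_year)),
      as.Date(sprintf("%d-12-31", start_year + n_years - 1L)), by = "day")
}

#' True attributable fraction under the generating surfaces
#'
#' Applies the backward attribution formula with the *true* surfaces of a
#' [simulation_truth()] instead of fitted coefficients: the recovery
#' target for the attribution machinery.  Cold and heat use the same
#' proportional allocation of each day's total non-optimal burden as
#' [split_cold_heat()].  Days with incomplete lag history are excluded.
#'
#' @param truth A [simulation_truth()].
#' @param tmean,ari Daily exposure series.
#' @param deaths Optional daily deaths for weighting; unweighted mean of
#'   daily AFs when omitted.
#' @param component One of `"cold"`, `"heat"`, `"temperature"`, `"ari"`.
#' @return True total attributable fraction (a number).
#' @export
true_attributable_fraction <- function(truth, tmean, ari = NULL,
                                       deaths = NULL,
                                       component = c("cold", "heat",
                                                     "temperature", "ari")) {
  component <- match.arg(component)
  gT <- lag_profile(truth$lag_scale_temp)
  L <- length(gT) - 1L
  n <- length(tmean)
  ok <- seq.int(L + 1L, n)
  cum_lagged <- function(x, fx, g) {
    Q <- lag_matrix(fx, length(g) - 1L)
    drop(Q %*% g)
  }
  af <- switch(component,
    ari = {
      gA <- lag_profile(truth$lag_scale_ari)
      1 - exp(-cum_lagged(ari, true_ari_curve(truth, ari), gA))
    },
    temperature = 1 - exp(-cum_lagged(tmean, true_temp_curve(truth, tmean), gT)),
    {
      a <- cum_lagged(tmean, true_temp_curve_cold(truth, tmean), gT)
      b <- cum_lagged(tmean, true_temp_curve_heat(truth, tmean), gT)
      tot <- 1 - exp(-(a + b))
      w <- ifelse(abs(a + b) > 0, a / (a + b), 0)
      if (component == "cold") tot * w else tot * (1 - w)
    })
  af <- af[ok]
  if (is.null(deaths)) mean(af) else {
    sum(af * deaths[ok]) / sum(deaths[ok])
  }
}
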