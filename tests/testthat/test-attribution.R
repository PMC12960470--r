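test_that("daily backward AF matches closed forms and masking rules", {
  n <- 80
  # constant exposure 2, a(x) = x, c(l) = 1, eta = 0.005: every lag
  # contributes log RR 0.01, so AF = 1 - exp(-0.22)
  x <- rep(2, n)
  fit <- make_toy_fit(0.005, matrix(1e-10), toy_var_spec(), toy_lag_spec(),
                      21L, x)
  af <- daily_backward_af(fit, center = 0)
  expect_true(all(is.na(af[1:21])))
  expect_equal(af[22:n], rep(1 - exp(-0.22), n - 21), tolerance = 1e-12)
  expect_equal(1 - exp(-0.22), 0.19748, tolerance = 1e-4)

  # zero coefficients: AF identically zero
  fit0 <- make_toy_fit(0, matrix(1e-10), toy_var_spec(), toy_lag_spec(),
                       21L, x)
  expect_equal(daily_backward_af(fit0, center = 0)[22:n], rep(0, n - 21))

  # exposure always outside the attribution range contributes nothing
  af_out <- daily_backward_af(fit, center = 0, range = c(5, 10))
  expect_equal(af_out[22:n], rep(0, n - 21))
})

test_that("daily AF equals a brute-force surface evaluation on a toy series", {
  set.seed(61)
  x <- runif(60, 0, 4)
  eta <- 0.004
  fit <- make_toy_fit(eta, matrix(1e-10), toy_var_spec(), toy_lag_spec(),
                      21L, x)
  s_fun <- function(z, l) eta * (z - 1) * 1
  for (rng in list(c(-Inf, Inf), c(1, 3))) {
    af <- daily_backward_af(fit, center = 1, range = rng)
    oracle <- brute_daily_af(x, 21L, s_fun, center = 1, range = rng)
    expect_equal(af, oracle, tolerance = 1e-12)
  }
})

test_that("attributable totals aggregate daily fractions by deaths", {
  expect_equal(attributable_summary(rep(0, 10), rep(100, 10)),
               list(af_total = 0, an_total = 0))
  s <- attributable_summary(rep(0.1, 100), rep(300, 100))
  expect_equal(s$af_total, 0.1)
  expect_equal(s$an_total, 3000)
  s2 <- attributable_summary(c(0.2, 0), c(100, 300))
  expect_equal(s2$an_total, 20)
  expect_equal(s2$af_total, 0.05)
  expect_error(attributable_summary(c(0.1), c(0)), "zero total deaths")
})

test_that("empirical intervals are seeded, collapse with zero covariance and widen with it", {
  set.seed(62)
  x <- runif(120, 0, 4)
  deaths <- rpois(120, 300)
  mk <- function(v) make_toy_fit(0.004, matrix(v), toy_var_spec(),
                                 toy_lag_spec(), 21L, x)
  r0 <- attribute_component(mk(1e-30), "temperature", deaths, center = 1,
                            n_sim = 400, seed = 7)
  expect_equal(unname(r0$af_low), r0$af_total, tolerance = 1e-4)
  expect_equal(unname(r0$af_high), r0$af_total, tolerance = 1e-4)

  r1 <- attribute_component(mk(1e-6), "temperature", deaths, center = 1,
                            n_sim = 400, seed = 7)
  r1b <- attribute_component(mk(1e-6), "temperature", deaths, center = 1,
                             n_sim = 400, seed = 7)
  expect_identical(r1[c("af_low", "af_high", "an_low", "an_high")],
                   r1b[c("af_low", "af_high", "an_low", "an_high")])

  r4 <- attribute_component(mk(4e-6), "temperature", deaths, center = 1,
                            n_sim = 400, seed = 7)
  expect_gt(r4$af_high - r4$af_low, r1$af_high - r1$af_low)
})

test_that("cold and heat split is exactly additive and respects one-sided series", {
  d <- sim_fixture(n_years = 3, seed = 63)
  fit <- fit_dlnm(d, temperature_cb_spec(d$tmean))
  mmt <- find_mmt(fit, n_sim = 0)$value
  ch <- split_cold_heat(fit, d$deaths, mmt, n_sim = 0)
  full <- daily_backward_af(fit, center = mmt)
  full_an <- attributable_summary(full, d$deaths)$an_total
  expect_equal(ch$cold$an_total + ch$heat$an_total, full_an,
               tolerance = 1e-8)
  ok <- !is.na(full)
  expect_equal(ch$cold$daily_an[ok] + ch$heat$daily_an[ok],
               full[ok] * d$deaths[ok], tolerance = 1e-10)

  # split point above every observation: cold carries the whole burden
  ch_hi <- split_cold_heat(fit, d$deaths, max(d$tmean) + 5, n_sim = 0)
  full_hi <- daily_backward_af(fit, center = max(d$tmean) + 5)
  expect_equal(ch_hi$heat$an_total, 0, tolerance = 1e-10)
  expect_equal(ch_hi$cold$an_total,
               attributable_summary(full_hi, d$deaths)$an_total,
               tolerance = 1e-8)

  # series entirely below the split point has no heat component
  x <- runif(100, 0, 4)
  deaths <- rpois(100, 300)
  fitt <- make_toy_fit(0.004, matrix(1e-8), toy_var_spec(), toy_lag_spec(),
                       21L, x)
  ch_toy <- split_cold_heat(fitt, deaths, 10, n_sim = 0)
  expect_equal(ch_toy$heat$an_total, 0, tolerance = 1e-12)
})

test_that("monthly pooling conserves the attributable total", {
  d <- sim_fixture(n_years = 3, seed = 64)
  fit <- fit_dlnm(d, temperature_cb_spec(d$tmean))
  mmt <- find_mmt(fit, n_sim = 0)$value
  ch <- split_cold_heat(fit, d$deaths, mmt, n_sim = 0)
  mo <- monthly_af(ch$cold$daily_an, d$deaths, d$date)
  expect_identical(nrow(mo), 12L)
  expect_equal(sum(mo$an), ch$cold$an_total, tolerance = 1e-8)
  expect_equal(mo$an, mo$af * mo$deaths, tolerance = 1e-10)

  # constant daily AF: every month reports the same fraction
  daily_an <- 0.07 * d$deaths
  mo_c <- monthly_af(daily_an, d$deaths, d$date)
  expect_equal(mo_c$af, rep(0.07, 12), tolerance = 1e-12)
})

test_that("estimated cold AF tracks the generating truth", {
  nrep <- 10
  inside <- logical(nrep)
  for (i in seq_len(nrep)) {
    d <- simulate_daily_series(6, seed = 6500 + i)
    tr <- attr(d, "truth")
    fit <- fit_dlnm(d, temperature_cb_spec(d$tmean),
                    ari_cb_spec(d$ari))
    ch <- split_cold_heat(fit, d$deaths, tr$mmt, n_sim = 300,
                          seed = i)
    truth_af <- true_attributable_fraction(tr, d$tmean, deaths = d$deaths,
                                           component = "cold")
    inside[i] <- truth_af >= ch$cold$af_low && truth_af <= ch$cold$af_high
  }
  expect_gte(mean(inside), 0.8)
})
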