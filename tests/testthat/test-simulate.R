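test_that("generated series are reproducible and structurally valid", {
  d1 <- simulate_daily_series(3, seed = 81)
  d2 <- simulate_daily_series(3, seed = 81)
  expect_identical(d1, d2)
  d3 <- simulate_daily_series(3, seed = 82)
  expect_false(identical(d1$deaths, d3$deaths))

  expect_false(anyNA(d1))
  expect_true(all(d1$deaths >= 0))
  expect_identical(d1$deaths, as.integer(round(d1$deaths)))
  expect_identical(nrow(d1), length(seq(d1$date[1], max(d1$date), by = "day")))
})

test_that("temperature generator hits the target climate", {
  # noiseless: pure sinusoid with known extremes
  t0 <- simulate_temperature(2, sd = 0, ar1 = 0, seed = 83)
  expect_equal(max(t0$tmean), 8.3 + 10, tolerance = 1e-3)
  expect_equal(min(t0$tmean), 8.3 - 10, tolerance = 1e-3)
  # July warmer than January
  july <- format(t0$date, "%m") == "07"
  jan <- format(t0$date, "%m") == "01"
  expect_gt(mean(t0$tmean[july]), mean(t0$tmean[jan]))

  t10 <- simulate_temperature(10, seed = 84)
  expect_gt(mean(t10$tmean), 7.8)
  expect_lt(mean(t10$tmean), 8.8)
})

test_that("ARI generator produces winter epidemics over an endemic floor", {
  a0 <- simulate_ari(3, epidemic_peak_mean = 90, peak_sdlog = 0, seed = 85)
  # no epidemic excess: flat at baseline up to reporting noise
  expect_lt(diff(range(a0$ari)) / 90, 0.5)

  a <- simulate_ari(10, seed = 86)
  expect_true(all(a$ari >= 30))
  high <- a$ari > 1.5 * 90
  mo <- as.integer(format(a$date, "%m"))
  expect_gte(mean(mo[high] %in% c(11, 12, 1, 2, 3)), 0.9)
})

test_that("mortality generator matches its baseline and cold raises winter deaths", {
  dts <- seq(as.Date("2000-01-01"), by = "day", length.out = 3650)
  null_truth <- simulation_truth(trend_slope = 0, seasonal_amplitude = 0,
                                 dow_effects = rep(0, 7), cold_coef = 0,
                                 heat_coef = 0, ari_slope = 0,
                                 ari_coupling = 0, baseline_log = log(315))
  y <- simulate_mortality(rnorm(3650, 8, 8), runif(3650, 34, 571), dts,
                          null_truth, seed = 87)
  expect_equal(mean(y), 315, tolerance = 0.02 * 315)

  d <- simulate_daily_series(10, seed = 88)
  mo <- as.integer(format(d$date, "%m"))
  expect_gt(mean(d$deaths[mo %in% c(12, 1, 2)]),
            mean(d$deaths[mo %in% c(6, 7, 8)]))
})

test_that("gamma frailty yields the requested overdispersion", {
  dts <- seq(as.Date("2000-01-01"), by = "day", length.out = 4000)
  null_truth <- simulation_truth(trend_slope = 0, seasonal_amplitude = 0,
                                 dow_effects = rep(0, 7), cold_coef = 0,
                                 heat_coef = 0, ari_slope = 0,
                                 ari_coupling = 0)
  y <- simulate_mortality(rep(10, 4000), rep(100, 4000), dts, null_truth,
                          overdispersion = 2, seed = 89)
  f <- fit_quasipoisson(matrix(1, 4000, 1), y)
  expect_gt(f$dispersion, 1.5)
  expect_lt(f$dispersion, 2.6)
})

test_that("truth oracle reproduces closed-form and additive burdens", {
  tr <- simulation_truth()
  # zero surfaces give zero attributable fraction
  tr0 <- simulation_truth(cold_coef = 0, heat_coef = 0, ari_slope = 0)
  x <- rnorm(400, 8, 8)
  expect_equal(true_attributable_fraction(tr0, x, component = "temperature"), 0)

  # constant cumulative log RR 0.22: AF = 1 - exp(-0.22)
  tr_ari <- simulation_truth(ari_slope = 0.22 / 100)
  af <- true_attributable_fraction(tr_ari, x, ari = rep(100, 400),
                                   component = "ari")
  expect_equal(af, 1 - exp(-0.22), tolerance = 1e-10)

  # cold + heat add up to the full temperature burden
  set.seed(90)
  x <- rnorm(600, 8, 8)
  deaths <- rpois(600, 300)
  af_c <- true_attributable_fraction(tr, x, deaths = deaths, component = "cold")
  af_h <- true_attributable_fraction(tr, x, deaths = deaths, component = "heat")
  af_t <- true_attributable_fraction(tr, x, deaths = deaths,
                                     component = "temperature")
  expect_equal(af_c + af_h, af_t, tolerance = 1e-10)

  # the true temperature curve is zero at the MMT and positive elsewhere
  expect_equal(true_temp_curve(tr, tr$mmt), 0)
  expect_true(all(true_temp_curve(tr, c(-10, 0, 10, 17, 19, 25)) > 0))
})
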