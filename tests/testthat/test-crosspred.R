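test_that("cumulative curve has unit RR at the centre and honours zero blocks", {
  set.seed(51)
  x <- rnorm(300, 8, 8)
  spec <- temperature_cb_spec(x)
  p <- 20L
  fit0 <- make_toy_fit(rep(0, p), diag(1e-4, p), spec$var_spec,
                       spec$lag_spec, spec$lag_max, x)
  er <- cumulative_exposure_response(fit0, at = c(-5, 0, 10, 20), center = 10)
  expect_equal(er$rr, rep(1, 4), tolerance = 1e-12)
  expect_true(all(er$se_log_rr[er$exposure != 10] > 0))
  # at the centre the CI collapses to the point
  at_c <- er[er$exposure == 10, ]
  expect_equal(at_c$se_log_rr, 0, tolerance = 1e-12)
  expect_equal(at_c$rr_low, 1, tolerance = 1e-12)
  expect_equal(at_c$rr_high, 1, tolerance = 1e-12)
})

test_that("toy J=K=1 model reproduces the closed-form cumulative RR", {
  x <- seq(-5, 25, length.out = 100)
  eta <- 0.003
  fit <- make_toy_fit(eta, matrix(1e-8), toy_var_spec(), toy_lag_spec(),
                      21L, x)
  er <- cumulative_exposure_response(fit, at = c(0, 5, 12), center = 10)
  expect_equal(er$rr, exp(22 * eta * (c(0, 5, 12) - 10)), tolerance = 1e-12)
  # and against the explicit summation over lags
  expect_equal(er$log_rr[1], brute_cum_log_rr(eta, 0, 10, 21),
               tolerance = 1e-12)
  # lag-specific slice matches the hand computation eta * (x - c) * c(l)
  lr <- lag_response_at(fit, x = 5, center = 10)
  expect_equal(lr, rep(eta * (5 - 10), 22), tolerance = 1e-12)
  expect_equal(lag_response_at(fit, x = 10, center = 10), rep(0, 22))
})

test_that("re-centering shifts the cumulative curve by a constant factor", {
  set.seed(52)
  x <- rnorm(400, 8, 8)
  spec <- temperature_cb_spec(x)
  eta <- rnorm(20, 0, 0.01)
  fit <- make_toy_fit(eta, diag(1e-6, 20), spec$var_spec, spec$lag_spec,
                      spec$lag_max, x)
  grid <- seq(-5, 22, length.out = 30)
  rr1 <- cumulative_exposure_response(fit, at = c(grid, 15), center = 5)$rr
  rr2 <- cumulative_exposure_response(fit, at = grid, center = 15)$rr
  expect_equal(rr1[seq_along(grid)] / rr1[length(grid) + 1], rr2,
               tolerance = 1e-10)
})

test_that("MMT is found for a constructed quadratic curve, with boundaries flagged", {
  set.seed(53)
  x <- rnorm(4000, 8, 8)
  spec <- temperature_cb_spec(x)
  grid <- seq(quantile(x, 0.005), quantile(x, 0.995), length.out = 120)
  eta <- curve_to_coef(spec, grid, function(z) (z - 18)^2 / 400)
  fit <- make_toy_fit(eta, diag(1e-10, 20), spec$var_spec, spec$lag_spec,
                      spec$lag_max, x)
  m <- find_mmt(fit, n_sim = 200, seed = 9)
  expect_lt(abs(m$value - 18), 0.5)
  expect_false(m$boundary)
  expect_true(m$ci_low <= m$value && m$value <= m$ci_high)

  # identical seed, identical interval
  m2 <- find_mmt(fit, n_sim = 200, seed = 9)
  expect_identical(m[c("value", "ci_low", "ci_high")],
                   m2[c("value", "ci_low", "ci_high")])

  # monotone decreasing curve: argmin sits on the upper search bound
  eta_dec <- curve_to_coef(spec, grid, function(z) -z / 50)
  fit_dec <- make_toy_fit(eta_dec, diag(1e-10, 20), spec$var_spec,
                          spec$lag_spec, spec$lag_max, x)
  m_dec <- find_mmt(fit_dec, n_sim = 0)
  expect_true(m_dec$boundary)
  expect_gt(m_dec$value, quantile(x, 0.97))

  # flat curve is rejected
  fit_flat <- make_toy_fit(rep(0, 20), diag(1e-10, 20), spec$var_spec,
                           spec$lag_spec, spec$lag_max, x)
  expect_error(find_mmt(fit_flat, n_sim = 0), "flat")
})

test_that("pointwise CIs on the cumulative curve cover a known truth", {
  # moderately sized replicate study: fit the temperature-only model to
  # data with a known curve and check 95% coverage at three percentiles
  set.seed(54)
  nrep <- 25
  hits <- matrix(NA, nrep, 3)
  for (i in seq_len(nrep)) {
    d <- simulate_daily_series(5, truth = simulation_truth(ari_slope = 0,
                                                           ari_coupling = 0),
                               seed = 5400 + i)
    tr <- attr(d, "truth")
    fit <- fit_dlnm(d, temperature_cb_spec(d$tmean))
    at <- quantile(d$tmean, c(0.01, 0.025, 0.975))
    er <- cumulative_exposure_response(fit, at = at, center = tr$mmt)
    truth <- true_temp_curve(tr, at)
    hits[i, ] <- truth >= er$log_rr - 1.96 * er$se_log_rr &
      truth <= er$log_rr + 1.96 * er$se_log_rr
  }
  expect_gte(mean(hits), 0.85)
})
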