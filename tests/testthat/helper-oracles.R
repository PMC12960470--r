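# Shared fixtures: toy fitted-model constructor and brute-force oracles.
# The oracles deliberately use plain loops over the bidimensional
# exposure-lag surface, independent of the matrix algebra in R/.

# a dlnm_fit-shaped object with a single cross-basis block, for testing
# prediction/attribution algebra with hand-picked coefficients
make_toy_fit <- function(eta, V, var_spec, lag_spec, lag_max, x,
                         term = "temperature") {
  spec <- cross_basis_spec(var_spec, lag_spec, lag_max)
  block <- if (term == "temperature") "cb_temperature" else "cb_ari"
  fit <- list(
    coefficients = eta, vcov = V,
    layout = stats::setNames(list(seq_along(eta)), block),
    terms = stats::setNames(
      list(list(spec = spec, x = x, block = block)), term),
    n_obs = length(x), n_params = length(eta)
  )
  class(fit) <- c("dlnm_fit", "qp_fit")
  fit
}

# J = K = 1 toy bases: exposure a(x) = x, lag c(l) = 1
toy_var_spec <- function() basis_spec("linear", intercept = FALSE)
toy_lag_spec <- function() basis_spec("constant")

# direct-loop cross-basis for arbitrary basis-function lists
brute_cross_basis <- function(x, a_funs, c_funs, lag_max) {
  n <- length(x)
  J <- length(a_funs); K <- length(c_funs)
  out <- matrix(NA_real_, n, J * K)
  for (t in seq.int(lag_max + 1L, n)) {
    for (j in seq_len(J)) for (k in seq_len(K)) {
      s <- 0
      for (l in 0:lag_max) s <- s + a_funs[[j]](x[t - l]) * c_funs[[k]](l)
      out[t, (j - 1L) * K + k] <- s
    }
  }
  out
}

# direct-loop cumulative log RR for the J = K = 1 toy
brute_cum_log_rr <- function(eta, x, center, lag_max) {
  s <- 0
  for (l in 0:lag_max) s <- s + eta * (x - center) * 1
  s
}

# direct-loop backward daily AF given the full surface s(x, l)
brute_daily_af <- function(x, lag_max, s_fun, center, range = c(-Inf, Inf)) {
  n <- length(x)
  af <- rep(NA_real_, n)
  for (t in seq.int(lag_max + 1L, n)) {
    tot <- 0
    for (l in 0:lag_max) {
      xi <- x[t - l]
      if (!(xi > range[1] && xi < range[2])) xi <- center
      tot <- tot + s_fun(xi, l)
    }
    af[t] <- 1 - exp(-tot)
  }
  af
}

# least-squares coefficients making a cross-basis block's cumulative curve
# approximate a target function on a grid (lag dimension carries weights
# u with sum(u * w) = 1 so the exposure shape is reproduced exactly)
curve_to_coef <- function(spec, grid, target) {
  A <- eval_basis(spec$var_spec, grid)
  beta <- stats::coef(stats::lm.fit(cbind(1, A), target(grid)))[-1]
  w <- cumulative_lag_weights(spec$lag_spec, spec$lag_max)
  u <- w / sum(w^2)
  as.vector(t(outer(beta, u)))     # eta[(j-1)K + k] = beta_j * u_k
}

# small daily series fixture for fitting tests (defaults trimmed for speed)
sim_fixture <- function(n_years = 4, seed = 1, ...) {
  simulate_daily_series(n_years, truth = simulation_truth(...), seed = seed)
}
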