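#' Natural spline basis for the long-term and seasonal trend
#'
#' Natural cubic spline of the day index with `round(df_per_year * years)`
#' degrees of freedom, interior knots at equally spaced quantiles of the
#' day index and boundary knots at the first and last day.  Nine degrees of
#' freedom per year is the conventional choice for jointly capturing slow
#' demographic trends and within-year seasonality in daily mortality
#' series; a 38-year record therefore receives 342 df.
#'
#' @param n_days Number of days.
#' @param years Span in years (defaults to `n_days / 365.25`).
#' @param df_per_year Degrees of freedom per year (default 9).
#' @return `n_days` by `df` basis matrix.
#' @export
time_trend_basis <- function(n_days, years = n_days / 365.25, df_per_year = 9) {
  if (n_days < 2) stop("`n_days` must be >= 2")
  df <- as.integer(round(df_per_year * years))
  if (df < 1) stop("requested trend df < 1")
  if (df >= n_days) stop("requested trend df must be < n_days")
  out <- if (df == 1L) {
    matrix(seq_len(n_days), ncol = 1L)
  } else {
    unname(as.matrix(splines::ns(seq_len(n_days), df = df)))
  }
  colnames(out) <- paste0("trend", seq_len(ncol(out)))
  out
}

#' Day-of-week indicator columns
#'
#' Treatment-coded indicators with Monday as the reference level.
#'
#' @param dates `Date` vector.
#' @return `length(dates)` by 6 0/1 matrix (Tue..Sun).
#' @export
dow_indicators <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  wd <- factor(format(dates, "%u"), levels = as.character(1:7),
               labels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  mm <- stats::model.matrix(~wd)[, -1L, drop = FALSE]
  colnames(mm) <- sub("^wd", "dow", colnames(mm))
  unname_rows(mm)
}

unname_rows <- function(m) {
  rownames(m) <- NULL
  m
}

#' Fit a quasi-Poisson regression
#'
#' Log-link Poisson-score regression fitted by iteratively reweighted least
#' squares (relative deviance tolerance 1e-9, at most 50 iterations), with
#' the dispersion estimated from Pearson residuals,
#' `phi = sum((y - mu)^2 / mu) / (n - p)`, and the coefficient covariance
#' scaled accordingly: `phi * (X' W X)^{-1}` with `W = diag(mu)`.
#'
#' @param design Numeric design matrix (should include an intercept column
#'   and have full column rank).
#' @param y Non-negative integer response aligned with `design` rows.
#' @param layout Optional named list of integer column spans identifying
#'   model blocks (e.g. `intercept`, `cb_temperature`, `cb_ari`, `trend`,
#'   `dow`), kept with the fit for block extraction.
#' @return An object of class `qp_fit` with elements `coefficients`,
#'   `vcov`, `dispersion`, `deviance`, `gcv`, `fitted`, `y`, `layout`,
#'   `n_obs`, `n_params`, `converged`.
#' @export
fit_quasipoisson <- function(design, y, layout = NULL) {
  design <- as.matrix(design)
  if (length(y) != nrow(design)) stop("`y` and `design` are not aligned")
  if (any(y < 0)) stop("`y` must be non-negative")
  n <- nrow(design)
  p <- ncol(design)
  if (qr(design)$rank < p) stop("design matrix is rank deficient")
  fit <- stats::glm.fit(design, y, family = stats::quasipoisson(),
                        control = stats::glm.control(epsilon = 1e-9,
                                                     maxit = 50L))
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance))
  }
  mu <- fit$fitted.values
  phi <- sum((y - mu)^2 / mu) / (n - p)
  xtwx <- crossprod(design * sqrt(mu))
  vcov <- phi * chol2inv(chol(xtwx))
  dimnames(vcov) <- list(colnames(design), colnames(design))
  beta <- stats::coef(fit)
  dev <- fit$deviance
  structure(
    list(coefficients = beta, vcov = vcov, dispersion = phi,
         deviance = dev, gcv = n * dev / (n - p)^2,
         fitted = mu, y = y, layout = layout,
         n_obs = n, n_params = p, converged = fit$converged,
         iter = fit$iter),
    class = "qp_fit"
  )
}

#' @export
print.qp_fit <- function(x, ...) {
  cat("<qp_fit> quasi-Poisson, ", x$n_obs, " obs, ", x$n_params,
      " params\n  deviance ", signif(x$deviance, 6), ", dispersion ",
      signif(x$dispersion, 4), ", GCV ", signif(x$gcv, 6), "\n", sep = "")
  invisible(x)
}

#' Generalized cross-validation score
#'
#' `GCV = n * D / (n - p)^2` with `D` the Poisson deviance and `p` the
#' parameter count; all model terms are unpenalized regression splines so
#' the effective degrees of freedom equal `p`.  Used to compare the model
#' with and without the ARI cross-basis.
#'
#' @param model A `qp_fit`.
#' @return The GCV score.
#' @export
gcv_score <- function(model) {
  stopifnot(inherits(model, "qp_fit"))
  if (model$n_params >= model$n_obs) stop("p >= n: GCV undefined")
  model$n_obs * model$deviance / (model$n_obs - model$n_params)^2
}

#' Fit the paired DLNM mortality models
#'
#' Builds the full design -- intercept, temperature cross-basis, optional
#' ARI cross-basis, long-term/seasonal trend spline and day-of-week
#' indicators -- and fits the quasi-Poisson regression of daily all-cause
#' deaths on it.  Rows with incomplete lag history (the first `lag_max`
#' days) are dropped; when both models of a mediation pair are fitted the
#' caller passes the same `rows` so they use identical observations.
#'
#' @param data Data frame with columns `date`, `deaths`, `tmean` and (if
#'   `ari_spec` is given) `ari`.
#' @param temp_spec [cross_basis_spec()] for temperature.
#' @param ari_spec Optional [cross_basis_spec()] for ARI incidence; `NULL`
#'   fits the temperature-only model.
#' @param trend_df_per_year Trend spline df per year (default 9).
#' @param rows Optional integer vector of rows (into `data`) to fit on;
#'   defaults to all rows with complete lag history.
#' @param extra Optional numeric matrix of additional linear covariate
#'   columns aligned with `data`.
#' @return A `dlnm_fit`: a `qp_fit` augmented with the cross-basis
#'   specifications and exposure series (element `terms`), the fitted row
#'   indices and the dates.
#' @export
fit_dlnm <- function(data, temp_spec, ari_spec = NULL,
                     trend_df_per_year = 9, rows = NULL, extra = NULL) {
  check_daily_series(data, need_ari = !is.null(ari_spec))
  n <- nrow(data)
  lag_max <- max(temp_spec$lag_max, if (!is.null(ari_spec)) ari_spec$lag_max else 0L)
  if (is.null(rows)) rows <- seq.int(lag_max + 1L, n)

  cb_t <- cross_basis(data$tmean, temp_spec)
  blocks <- list(intercept = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                 cb_temperature = unclass(cb_t))
  if (!is.null(ari_spec)) {
    cb_a <- cross_basis(data$ari, ari_spec)
    colnames(cb_a) <- paste0("ari.", colnames(cb_a))
    blocks$cb_ari <- unclass(cb_a)
  }
  blocks$trend <- time_trend_basis(n, df_per_year = trend_df_per_year)
  blocks$dow <- dow_indicators(data$date)
  if (!is.null(extra)) blocks$extra <- as.matrix(extra)

  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  layout <- stats::setNames(
    purrr::map2(ends - widths + 1L, ends, seq.int), names(blocks))

  design <- do.call(cbind, blocks)[rows, , drop = FALSE]
  fit <- fit_quasipoisson(design, data$deaths[rows], layout = layout)
  fit$terms <- list(
    temperature = list(spec = temp_spec, x = data$tmean, block = "cb_temperature"),
    ari = if (!is.null(ari_spec)) list(spec = ari_spec, x = data$ari,
                                       block = "cb_ari")
  )
  fit$rows <- rows
  fit$dates <- data$date
  class(fit) <- c("dlnm_fit", class(fit))
  fit
}

check_daily_series <- function(data, need_ari = TRUE) {
  need <- c("date", "deaths", "tmean", if (need_ari) "ari")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data is missing columns: ", paste(miss, collapse = ", "))
  if (!inherits(data$date, "Date")) stop("`date` must be a Date column")
  if (anyNA(data[need])) stop("daily series must have no missing values")
  if (any(data$deaths < 0) || any(data$deaths != round(data$deaths))) {
    stop("`deaths` must be non-negative integers")
  }
  invisible(data)
}

block_indices <- function(model, block) {
  idx <- model$layout[[block]]
  if (is.null(idx)) stop("model has no block '", block, "'")
  idx
}

term_info <- function(model, term = c("temperature", "ari")) {
  term <- match.arg(term)
  info <- model$terms[[term]]
  if (is.null(info)) stop("model was fitted without the ", term, " term")
  info
}
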