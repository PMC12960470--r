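#' Analysis configuration
#'
#' Collects every tunable setting of the paired-model mediation analysis.
#' Defaults are the conventional choices for national daily mortality
#' series: 21-day lag window, temperature exposure knots at the 10th/75th/
#' 90th percentiles with two log-spaced lag knots, four equally spaced ARI
#' exposure knots with one lag knot, a trend spline with 9 df per year,
#' 19-year moving windows, and 1000 Monte-Carlo draws for the MMT and
#' attribution intervals.
#'
#' @param lag_max Maximum lag in days.
#' @param temp_knot_percentiles Temperature exposure knot percentiles.
#' @param temp_lag_knots Number of log-spaced temperature lag knots.
#' @param ari_knots Number of equally spaced ARI exposure knots.
#' @param ari_lag_knots Number of ARI lag knots.
#' @param ari_knot_style `"range"` or `"percentile"` ARI knot placement.
#' @param trend_df_per_year Trend spline degrees of freedom per year.
#' @param window_years Length of moving analysis windows (years).
#' @param rr_percentiles Temperature percentiles reported in the RR table.
#' @param mmt_search_percentiles Search bounds for the MMT grid.
#' @param n_sim Monte-Carlo draws for empirical and MMT intervals.
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `mediation_config`.
#' @export
mediation_config <- function(lag_max = 21L,
                             temp_knot_percentiles = c(10, 75, 90),
                             temp_lag_knots = 2L,
                             ari_knots = 4L,
                             ari_lag_knots = 1L,
                             ari_knot_style = "range",
                             trend_df_per_year = 9,
                             window_years = 19L,
                             rr_percentiles = c(1, 2.5, 5, 97.5, 99),
                             mmt_search_percentiles = c(1, 99),
                             n_sim = 1000L,
                             seed = 1L) {
  cfg <- list(lag_max = as.integer(lag_max),
              temp_knot_percentiles = temp_knot_percentiles,
              temp_lag_knots = as.integer(temp_lag_knots),
              ari_knots = as.integer(ari_knots),
              ari_lag_knots = as.integer(ari_lag_knots),
              ari_knot_style = ari_knot_style,
              trend_df_per_year = trend_df_per_year,
              window_years = as.integer(window_years),
              rr_percentiles = rr_percentiles,
              mmt_search_percentiles = mmt_search_percentiles,
              n_sim = as.integer(n_sim), seed = as.integer(seed))
  stopifnot(cfg$lag_max >= 0, cfg$n_sim >= 0, cfg$window_years >= 1,
            all(cfg$temp_knot_percentiles > 0 & cfg$temp_knot_percentiles < 100))
  class(cfg) <- "mediation_config"
  cfg
}

#' Paired-model mediation analysis of temperature, ARI and mortality
#'
#' Fits the temperature-only model and the temperature + ARI model on the
#' identical set of days (those with complete 21-day exposure history for
#' both exposures), estimates each model's own minimum mortality
#' temperature, tabulates cumulative relative risks at the configured
#' temperature percentiles, computes the cold, heat and (for the ARI
#' model) ARI attributable burdens with empirical intervals, and derives
#' the mediated share of the cold burden:
#' `(cold AN without ARI - cold AN with ARI) / cold AN without ARI`.
#'
#' @param data Daily series: columns `date`, `deaths`, `tmean`, `ari`.
#' @param config A [mediation_config()].
#' @return An object of class `mediation_report`; see [tidy.mediation_report()]
#'   and [glance.mediation_report()].
#' @export
run_mediation <- function(data, config = mediation_config()) {
  check_daily_series(data)
  if (nrow(data) < 2 * 365) stop("need at least two years of daily data")
  temp_spec <- temperature_cb_spec(data$tmean, config$temp_knot_percentiles,
                                   config$lag_max, config$temp_lag_knots)
  ari_spec <- ari_cb_spec(data$ari, config$ari_knots, config$lag_max,
                          config$ari_lag_knots, config$ari_knot_style)
  rows <- seq.int(config$lag_max + 1L, nrow(data))

  fit0 <- fit_dlnm(data, temp_spec, NULL,
                   trend_df_per_year = config$trend_df_per_year, rows = rows)
  fit1 <- fit_dlnm(data, temp_spec, ari_spec,
                   trend_df_per_year = config$trend_df_per_year, rows = rows)
  stopifnot(identical(fit0$rows, fit1$rows))

  mmt0 <- find_mmt(fit0, search_percentiles = config$mmt_search_percentiles,
                   n_sim = config$n_sim, seed = config$seed)
  mmt1 <- find_mmt(fit1, search_percentiles = config$mmt_search_percentiles,
                   n_sim = config$n_sim, seed = config$seed)

  pct <- config$rr_percentiles
  tvals <- stats::quantile(data$tmean, pct / 100, names = FALSE)
  rr_tab <- dplyr::bind_rows(
    cumulative_exposure_response(fit0, at = tvals, center = mmt0$value) |>
      tibble::as_tibble() |>
      dplyr::mutate(model = "no_ari", percentile = pct),
    cumulative_exposure_response(fit1, at = tvals, center = mmt1$value) |>
      tibble::as_tibble() |>
      dplyr::mutate(model = "ari", percentile = pct)
  ) |>
    dplyr::select("model", "percentile", temperature = "exposure",
                  "rr", "rr_low", "rr_high")

  ch0 <- split_cold_heat(fit0, data$deaths, mmt0$value,
                         n_sim = config$n_sim, seed = config$seed + 1L)
  ch1 <- split_cold_heat(fit1, data$deaths, mmt1$value,
                         n_sim = config$n_sim, seed = config$seed + 2L)
  ari_attr <- attribute_component(fit1, "ari", data$deaths, center = 0,
                                  component = "ari",
                                  n_sim = config$n_sim,
                                  seed = config$seed + 3L)
  attribution <- list(
    no_ari = list(cold = ch0$cold, heat = ch0$heat),
    ari = list(cold = ch1$cold, heat = ch1$heat, ari = ari_attr)
  )
  cold0 <- ch0$cold$an_total
  mediated_share <- if (cold0 > 0) (cold0 - ch1$cold$an_total) / cold0 else NA_real_

  structure(
    list(models = list(no_ari = fit0, ari = fit1),
         mmt = list(no_ari = mmt0, ari = mmt1),
         rr_table = rr_tab,
         attribution = attribution,
         mediated_share = mediated_share,
         gcv = c(no_ari = fit0$gcv, ari = fit1$gcv),
         deaths = data$deaths, dates = data$date,
         config = config, n_days = nrow(data)),
    class = "mediation_report"
  )
}

#' @export
print.mediation_report <- function(x, ...) {
  cat("<mediation_report> ", x$n_days, " days (",
      format(min(x$dates)), " .. ", format(max(x$dates)), ")\n", sep = "")
  cat(sprintf("  MMT: %.1f degC (no-ARI) vs %.1f degC (ARI)\n",
              x$mmt$no_ari$value, x$mmt$ari$value))
  cat(sprintf("  GCV: %.4f (no-ARI) vs %.4f (ARI)\n",
              x$gcv["no_ari"], x$gcv["ari"]))
  for (m in names(x$attribution)) {
    for (comp in names(x$attribution[[m]])) {
      r <- x$attribution[[m]][[comp]]
      cat(sprintf("  [%s] %-4s AF %.2f%% (%.2f, %.2f)  AN %.0f\n",
                  m, comp, 100 * r$af_total, 100 * r$af_low,
                  100 * r$af_high, r$an_total))
    }
  }
  cat(sprintf("  mediated share of cold burden: %.1f%%\n",
              100 * x$mediated_share))
  invisible(x)
}

#' Tidy the attribution table of a mediation report
#'
#' @param x A `mediation_report`.
#' @param ... Unused.
#' @return Tibble with one row per model x component: `model`, `component`,
#'   `af`, `af_low`, `af_high`, `an`, `an_low`, `an_high`.
#' @method tidy mediation_report
#' @export
tidy.mediation_report <- function(x, ...) {
  purrr::imap(x$attribution, function(comps, m) {
    dplyr::bind_rows(purrr::map(comps, tidy)) |>
      dplyr::mutate(model = m, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' One-row summary of a mediation report
#'
#' @param x A `mediation_report`.
#' @param ... Unused.
#' @return One-row tibble: MMTs, GCVs, cold/heat/ARI AFs, mediated share.
#' @importFrom generics glance
#' @method glance mediation_report
#' @export
glance.mediation_report <- function(x, ...) {
  tibble::tibble(
    n_days = x$n_days,
    mmt_no_ari = x$mmt$no_ari$value,
    mmt_ari = x$mmt$ari$value,
    gcv_no_ari = unname(x$gcv["no_ari"]),
    gcv_ari = unname(x$gcv["ari"]),
    cold_af_no_ari = x$attribution$no_ari$cold$af_total,
    cold_af_ari = x$attribution$ari$cold$af_total,
    heat_af_no_ari = x$attribution$no_ari$heat$af_total,
    heat_af_ari = x$attribution$ari$heat$af_total,
    ari_af = x$attribution$ari$ari$af_total,
    mediated_share = x$mediated_share
  )
}

#' Moving-window mediation analyses
#'
#' Re-runs [run_mediation()] on every contiguous window of
#' `config$window_years` calendar years, advancing one year at a time
#' (a 38-year record with 19-year windows yields 20 analyses).  Knots,
#' trend df and MMT are re-derived inside each window from its own data.
#'
#' @inheritParams run_mediation
#' @return Tibble with columns `window` (label `"start-end"`),
#'   `start_year`, `end_year`, the [glance.mediation_report()] columns,
#'   and a list-column `report`.
#' @export
moving_windows <- function(data, config = mediation_config()) {
  yrs <- as.integer(format(data$date, "%Y"))
  spans <- window_spans(data$date, config$window_years)
  purrr::pmap_dfr(spans, function(window, start_year, end_year) {
    s <- start_year
    sub <- data[yrs >= s & yrs <= end_year, , drop = FALSE]
    rep <- run_mediation(sub, config)
    dplyr::bind_cols(
      tibble::tibble(window = window, start_year = start_year,
                     end_year = end_year),
      glance(rep),
      tibble::tibble(report = list(rep))
    )
  })
}

#' Enumerate moving analysis windows
#'
#' Contiguous windows of `window_years` calendar years advancing one year
#' at a time over the span of `dates` (e.g. 1982--2019 with 19-year
#' windows gives 1982-2000, 1983-2001, ..., 2001-2019: 20 windows).
#'
#' @param dates `Date` vector covering the analysis span.
#' @param window_years Window length in years.
#' @return Tibble with columns `window`, `start_year`, `end_year`.
#' @export
window_spans <- function(dates, window_years) {
  yrs <- as.integer(format(dates, "%Y"))
  y0 <- min(yrs); y1 <- max(yrs)
  w <- as.integer(window_years)
  if (y1 - y0 + 1L < w) stop("data span shorter than the window length")
  starts <- y0:(y1 - w + 1L)
  tibble::tibble(window = sprintf("%d-%d", starts, starts + w - 1L),
                 start_year = starts, end_year = starts + w - 1L)
}

#' Monthly attributable fractions from a mediation report
#'
#' Pools the daily attributable deaths of every model/component by
#' calendar month across all years of the analysis period.
#'
#' @param report A `mediation_report`.
#' @return Tibble with columns `model`, `component`, `month`, `af`, `an`,
#'   `deaths`.
#' @export
monthly_report <- function(report) {
  stopifnot(inherits(report, "mediation_report"))
  purrr::imap_dfr(report$attribution, function(comps, m) {
    purrr::imap_dfr(comps, function(r, comp) {
      monthly_af(r$daily_an, report$deaths, report$dates) |>
        dplyr::mutate(model = m, component = comp, .before = 1)
    })
  })
}

#' Plot the paired cumulative temperature-mortality curves
#'
#' @param object A `mediation_report`.
#' @param at Temperature grid (defaults to 100 points over the fitted range).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_report
#' @export
autoplot.mediation_report <- function(object, at = NULL, ...) {
  curves <- purrr::imap_dfr(object$models, function(fit, m) {
    cumulative_exposure_response(fit, at = at,
                                 center = object$mmt[[m]]$value) |>
      tibble::as_tibble() |>
      dplyr::mutate(model = m)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$exposure, y = .data$rr,
                                       colour = .data$model,
                                       fill = .data$model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rr_low,
                                      ymax = .data$rr_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Daily mean temperature (°C)",
                  y = "Relative risk (cumulative, lags 0–21)",
                  colour = "model", fill = "model") +
    ggplot2::theme_minimal()
}

#' Export a mediation report as delimited text files
#'
#' Writes the RR table, the attribution summary and the monthly AF table
#' as headered CSV files into `dir`.
#'
#' @param report A `mediation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("rr_table.csv", "attribution.csv",
                            "monthly_af.csv"))
  utils::write.csv(report$rr_table, paths[1], row.names = FALSE)
  utils::write.csv(tidy(report), paths[2], row.names = FALSE)
  utils::write.csv(monthly_report(report), paths[3], row.names = FALSE)
  invisible(paths)
}
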