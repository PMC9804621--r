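#' Configuration for the space-for-time response scenarios
#'
#' Describes a conceptual experiment: a set of sites that differ in baseline
#' temperature, a timeline of periods each containing several years, shared
#' period-level shifts and year-level anomalies, and a species response type.
#' Species abundance responds linearly through two channels: a slow channel
#' tracking the long-term (period-average) temperature, optionally delayed,
#' and a fast channel tracking the current year's temperature. `mixed`
#' species use both channels, typically with opposite signs.
#'
#' @param site_temps numeric vector of baseline site temperatures (degrees C;
#'   at least 2 distinct values).
#' @param n_periods number of periods.
#' @param years_per_period years per period.
#' @param period_shift numeric vector (length `n_periods`) of temperature
#'   shifts shared by all sites, relative to baseline; defaults to a step
#'   change of +2 degrees from period 2 onward.
#' @param annual_anomaly numeric vector (length `n_periods * years_per_period`)
#'   of year-level temperature anomalies shared by all sites; defaults to an
#'   alternating +/-0.5 degree pattern from period 2 onward (period 1, the
#'   baseline snapshot, is kept anomaly-free).
#' @param response `"slow_immediate"`, `"slow_delayed"`, `"fast"`, `"mixed"`.
#' @param delay response delay in periods (slow channel; > 0 only for
#'   `slow_delayed` and `mixed`).
#' @param slope_slow,slope_fast abundance change per degree C in each
#'   channel (`mixed` requires both nonzero).
#' @param intercept baseline abundance at temperature 0.
#' @param slow_window number of trailing periods averaged by the slow
#'   channel (default 1: the single period `delay` periods back).
#' @param noise_sd SD of additive abundance noise (default 0, the noiseless
#'   conceptual setting).
#' @param seed seed for the noise draws.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(site_temps = c(4, 6, 8, 10, 12),
                            n_periods = 6L, years_per_period = 4L,
                            period_shift = NULL, annual_anomaly = NULL,
                            response = c("slow_immediate", "slow_delayed",
                                         "fast", "mixed"),
                            delay = 0L, slope_slow = -2, slope_fast = 1,
                            intercept = 40, slow_window = 1L,
                            noise_sd = 0, seed = 1L) {
  response <- match.arg(response)
  if (length(unique(site_temps)) < 2L) stop("need >= 2 distinct site temperatures")
  n_periods <- as.integer(n_periods)
  years_per_period <- as.integer(years_per_period)
  delay <- as.integer(delay)
  if (delay < 0L) stop("delay must be >= 0")
  if (response == "slow_immediate" && delay != 0L)
    stop("slow_immediate means delay = 0; use slow_delayed")
  if (response == "mixed" && (slope_slow == 0 || slope_fast == 0))
    stop("mixed response requires both slopes nonzero")
  if (is.null(period_shift)) period_shift <- c(0, rep(2, n_periods - 1L))
  if (length(period_shift) != n_periods) stop("period_shift length mismatch")
  n_years <- n_periods * years_per_period
  if (is.null(annual_anomaly)) {
    annual_anomaly <- rep_len(c(0.5, -0.5), n_years)
    annual_anomaly[seq_len(years_per_period)] <- 0
  }
  if (length(annual_anomaly) != n_years) stop("annual_anomaly length mismatch")
  structure(
    list(site_temps = site_temps, n_periods = n_periods,
         years_per_period = years_per_period, period_shift = period_shift,
         annual_anomaly = annual_anomaly, response = response, delay = delay,
         slope_slow = slope_slow, slope_fast = slope_fast,
         intercept = intercept, slow_window = as.integer(slow_window),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "scenario_config")
}

# long site x year temperature/period table for a scenario
.scenario_frame <- function(config) {
  n_years <- config$n_periods * config$years_per_period
  period <- rep(seq_len(config$n_periods), each = config$years_per_period)
  data.frame(
    site = rep(seq_along(config$site_temps), each = n_years),
    year = rep(seq_len(n_years), times = length(config$site_temps)),
    period = rep(period, times = length(config$site_temps)),
    temp = rep(config$site_temps, each = n_years) +
      config$period_shift[rep(period, times = length(config$site_temps))] +
      rep(config$annual_anomaly, times = length(config$site_temps)))
}

# slow-channel driver: mean period-average temperature over the
# `slow_window` periods ending `delay` periods back (clamped at period 1)
.slow_driver <- function(config, site) {
  pmean <- config$site_temps[site] + config$period_shift  # per period
  vapply(seq_len(config$n_periods), function(p) {
    hi <- max(1L, p - config$delay)
    lo <- max(1L, hi - config$slow_window + 1L)
    mean(pmean[lo:hi])
  }, numeric(1))
}

#' Simulate species abundance under a response scenario
#'
#' Produces the "truth" series: per site and year, abundance =
#' intercept + slow channel + fast channel + optional noise, floored at 0.
#' The slow channel responds to the (possibly delayed) long-term average
#' temperature; the fast channel to the current year's temperature; which
#' channels are active depends on the configured response type.
#'
#' @param config a [scenario_config()].
#' @return Data frame `site`, `year`, `period`, `temp`, `abundance`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  fr <- .scenario_frame(config)
  slow_on <- config$response %in% c("slow_immediate", "slow_delayed", "mixed")
  fast_on <- config$response %in% c("fast", "mixed")
  ab <- rep(config$intercept, nrow(fr))
  if (slow_on) {
    sd_mat <- vapply(seq_along(config$site_temps), function(s) .slow_driver(config, s),
                     numeric(config$n_periods))  # periods x sites
    ab <- ab + config$slope_slow * sd_mat[cbind(fr$period, fr$site)]
  }
  if (fast_on) ab <- ab + config$slope_fast * fr$temp
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    ab <- ab + stats::rnorm(length(ab), 0, config$noise_sd)
  }
  fr$abundance <- pmax(ab, 0)
  fr
}

#' Space-for-time forecast from the baseline snapshot
#'
#' Fits the cross-site abundance-temperature relation by least squares on
#' the period-1 data (site means over the period's years) and projects it
#' forward. The forecast is identical for every response type by
#' construction: `static` mode applies the fitted line to period-average
#' temperatures (one forecast per site and period, repeated over the
#' period's years); `dynamic` mode applies it to each year's temperature.
#'
#' @param config a [scenario_config()].
#' @param truth simulated truth from [simulate_scenario()] (supplies the
#'   baseline abundances); defaults to simulating from `config`.
#' @param mode `"static"` or `"dynamic"`.
#' @return Data frame `site`, `year`, `period`, `forecast`.
#' @export
sft_forecast <- function(config, truth = simulate_scenario(config),
                         mode = c("static", "dynamic")) {
  mode <- match.arg(mode)
  base <- truth[truth$period == 1L, , drop = FALSE]
  bt <- tapply(base$temp, base$site, mean)
  ba <- tapply(base$abundance, base$site, mean)
  if (length(unique(bt)) < 2L)
    stop("fewer than 2 distinct baseline temperatures; cannot fit the relation")
  cf <- stats::coef(stats::lm(ba ~ bt))
  fr <- truth[c("site", "year", "period", "temp")]
  if (mode == "static") {
    ptemp <- stats::aggregate(temp ~ site + period, fr, mean)
    names(ptemp)[names(ptemp) == "temp"] <- "period_temp"
    fr <- merge(fr, ptemp, by = c("site", "period"), sort = FALSE)
    fr$forecast <- pmax(cf[1] + cf[2] * fr$period_temp, 0)
    fr$period_temp <- NULL
  } else {
    fr$forecast <- pmax(cf[1] + cf[2] * fr$temp, 0)
  }
  fr[order(fr$site, fr$year), c("site", "year", "period", "forecast")]
}

#' Flag periods/years where a space-for-time forecast is valid
#'
#' A period (static mode compares period-average truth) or year (dynamic
#' mode) is valid when the maximum relative error across sites is at most
#' `tolerance`. The noiseless conceptual scenarios use an effectively exact
#' tolerance by default.
#'
#' @param truth output of [simulate_scenario()].
#' @param forecast output of [sft_forecast()].
#' @param mode `"static"` or `"dynamic"` (granularity of the flags).
#' @param tolerance maximum relative error (default 1e-8; use e.g. 0.05
#'   with noisy simulations).
#' @return Data frame with `period` (or `year`) and logical `valid`.
#' @export
assess_validity <- function(truth, forecast, mode = c("static", "dynamic"),
                            tolerance = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(nrow(truth) == nrow(forecast))
  m <- merge(truth, forecast, by = c("site", "year", "period"))
  relerr <- abs(m$forecast - m$abundance) / pmax(abs(m$abundance), 1e-12)
  if (mode == "dynamic") {
    agg <- stats::aggregate(relerr, list(year = m$year), max)
    data.frame(year = agg$year, valid = agg$x <= tolerance)
  } else {
    # compare period-average truth with the (per-period constant) forecast
    ta <- stats::aggregate(abundance ~ site + period, m, mean)
    fa <- stats::aggregate(forecast ~ site + period, m, mean)
    mm <- merge(ta, fa, by = c("site", "period"))
    re <- abs(mm$forecast - mm$abundance) / pmax(abs(mm$abundance), 1e-12)
    agg <- stats::aggregate(re, list(period = mm$period), max)
    data.frame(period = agg$period, valid = agg$x <= tolerance)
  }
}

#' Validity truth table over response types and forecast modes
#'
#' Convenience wrapper running all four response types under both forecast
#' modes with a common scenario timeline, returning the per-period (static)
#' or per-year (dynamic) validity flags.
#'
#' @param delay delay in periods for the delayed/mixed responses.
#' @param ... passed to [scenario_config()].
#' @return Named list `static` / `dynamic` of named lists of validity data
#'   frames per response type.
#' @export
scenario_truth_table <- function(delay = 2L, ...) {
  types <- c("slow_immediate", "slow_delayed", "fast", "mixed")
  out <- list(static = list(), dynamic = list())
  for (tp in types) {
    cfg <- scenario_config(response = tp,
                           delay = if (tp %in% c("slow_delayed", "mixed")) delay else 0L,
                           ...)
    tr <- simulate_scenario(cfg)
    for (mode in c("static", "dynamic")) {
      fc <- sft_forecast(cfg, tr, mode = mode)
      out[[mode]][[tp]] <- assess_validity(tr, fc, mode = mode)
    }
  }
  out
}
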