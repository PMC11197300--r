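#' Growing degree hours response
#'
#' Hourly heat accumulation as a function of temperature: zero at or below the
#' base temperature `Tb` and at or above the critical temperature `Tc`, rising
#' along a cosine to a maximum of `Tu - Tb` at the optimum `Tu`, then falling
#' along a quarter cosine. Continuous everywhere.
#'
#' @param temp temperature(s), degrees C. Vectorized.
#' @param params a [phenoflex_params()] object.
#' @return GDH accumulated in one hour at each temperature.
#' @export
gdh_value <- function(temp, params) {
  params <- as_phenoflex_params(params)
  gdh_value_cpp(as.numeric(temp), params[["Tu"]], params[["Tb"]],
                params[["Tc"]])
}

#' One hourly step of the dynamic chill model
#'
#' Advances the precursor to the dormancy-breaking factor (PDBF) by one hour
#' at temperature `temp` and returns the chill portions produced. The
#' precursor relaxes towards its temperature-dependent steady state
#' `xs = (A0/A1) exp(-(E0-E1)/T_K)` at rate `k1 = A1 exp(-E1/T_K)` (`T_K` in
#' Kelvin). When the intermediate completes (`x* >= 1`), a sigmoidal fraction
#' `1 / (1 + exp(-slope (T - Tf)))` is converted irreversibly to chill
#' portions and removed from the pool.
#'
#' @param x current precursor level (>= 0).
#' @param temp temperature for the hour, degrees C.
#' @param params a [phenoflex_params()] object.
#' @return list with `x` (updated precursor) and `delta` (chill portions
#'   produced this hour).
#' @export
chill_step <- function(x, temp, params) {
  params <- as_phenoflex_params(params)
  stopifnot(x >= 0)
  TK <- temp + 273.15
  xs <- (params[["A0"]] / params[["A1"]]) *
    exp(-(params[["E0"]] - params[["E1"]]) / TK)
  k1 <- params[["A1"]] * exp(-params[["E1"]] / TK)
  xst <- xs - (xs - x) * exp(-k1)
  if (xst >= 1) {
    sig <- 1 / (1 + exp(-params[["slope"]] * (temp - params[["Tf"]])))
    delta <- xst * sig
    list(x = xst - delta, delta = delta)
  } else {
    list(x = xst, delta = 0)
  }
}

#' Chill-to-heat transition weight
#'
#' Fraction of the hourly GDH that counts towards the heat requirement, as a
#' function of accumulated chill portions `y`: `min(1, exp(s1 (y - yc)))`.
#' Monotone non-decreasing in `y`, reaching 1 at the chill requirement `yc`.
#'
#' @param y accumulated chill portions (>= 0). Vectorized.
#' @param params a [phenoflex_params()] object.
#' @return weight(s) in `[0, 1]`.
#' @export
heat_weight <- function(y, params) {
  params <- as_phenoflex_params(params)
  stopifnot(all(y >= 0))
  pmin(1, exp(params[["s1"]] * (y - params[["yc"]])))
}

# Internal: subset an hourly series to the season window and return the
# temperature vector, the per-day day-of-year map (relative to 1 January of
# the bloom year) and the dates.
prep_season <- function(hourly, season_start, check_coverage = TRUE) {
  stopifnot(all(c("date", "hour", "temp") %in% names(hourly)))
  dates <- unique(hourly$date)
  bloom_year <- as.integer(format(max(dates), "%Y"))
  if (is.null(season_start))
    season_start <- as.Date(sprintf("%d-08-01", bloom_year - 1L))
  keep <- hourly$date >= season_start
  if (!any(keep))
    stop("hourly series does not reach season start ", format(season_start))
  h <- hourly[keep, , drop = FALSE]
  if (check_coverage) {
    need_end <- as.Date(sprintf("%d-06-30", bloom_year))
    if (min(h$date) > season_start || max(h$date) < need_end)
      stop(sprintf(
        "hourly series must cover %s through %s; it spans %s to %s",
        format(season_start), format(need_end), format(min(h$date)),
        format(max(h$date))))
  }
  days <- sort(unique(h$date))
  jan1 <- as.Date(sprintf("%d-01-01", bloom_year))
  list(temp = h$temp[order(h$date, h$hour)],
       day_doy = as.numeric(days - jan1) + 1,
       days = days, bloom_year = bloom_year)
}

#' Predict a bloom date from hourly temperatures
#'
#' Runs the kinetic model hour by hour from `season_start` with zero chill,
#' heat and precursor state. Each hour the chill state is advanced first, then
#' the hourly GDH (weighted by [heat_weight()]) is added to the heat sum `z`.
#' The first hour with `z >= zc` is the bloom hour.
#'
#' @param hourly data frame with columns `date` (Date), `hour` (0--23) and
#'   `temp` (degrees C), as produced by [daily_to_hourly()].
#' @param params a [phenoflex_params()] object.
#' @param season_start first day of the model run. Defaults to 1 August of the
#'   year before the last year in the series, so an autumn-to-summer dormancy
#'   season is covered.
#' @param check_coverage require the series to span `season_start` through
#'   30 June of the bloom year. Disable for idealized short series.
#' @param keep_trajectory retain the full hourly chill (`y`) and heat (`z`)
#'   trajectories.
#' @return list of class `"bloom_prediction"` with elements `bloomed`
#'   (logical), `bloom_doy` (day of year relative to 1 January of the bloom
#'   year; `NA` if the season ends first), `bloom_date`, `bloom_hour` (index
#'   into the run), `state` (named `x`, `y`, `z` at the end of the run) and,
#'   optionally, `trajectory`.
#' @export
predict_bloom <- function(hourly, params, season_start = NULL,
                          check_coverage = TRUE, keep_trajectory = FALSE) {
  params <- as_phenoflex_params(params)
  prep <- prep_season(hourly, season_start, check_coverage)
  res <- pf_run_cpp(prep$temp, as.numeric(params), keep_traj = keep_trajectory)
  bloomed <- res$bloom_hour > 0
  day_idx <- if (bloomed) ceiling(res$bloom_hour / 24) else NA_integer_
  out <- list(
    bloomed = bloomed,
    bloom_doy = if (bloomed) prep$day_doy[day_idx] else NA_real_,
    bloom_date = if (bloomed) prep$days[day_idx] else as.Date(NA),
    bloom_hour = if (bloomed) res$bloom_hour else NA_integer_,
    state = c(x = res$x, y = res$y, z = res$z),
    bloom_year = prep$bloom_year
  )
  if (keep_trajectory)
    out$trajectory <- data.frame(hour = seq_along(res$y_traj),
                                 y = res$y_traj, z = res$z_traj)
  class(out) <- "bloom_prediction"
  out
}

#' @export
print.bloom_prediction <- function(x, ...) {
  if (x$bloomed)
    cat(sprintf("bloom on %s (day %g); final state y = %.2f, z = %.2f\n",
                format(x$bloom_date), x$bloom_doy, x$state[["y"]],
                x$state[["z"]]))
  else
    cat(sprintf("no bloom before the end of the series (y = %.2f, z = %.2f)\n",
                x$state[["y"]], x$state[["z"]]))
  invisible(x)
}

#' Temperature response curves
#'
#' `chill_response_curve()` reports accumulated chill portions after a fixed
#' number of hours at each constant temperature; `heat_response_curve()`
#' reports the hourly GDH response. The chill curve's peak is the effective
#' optimum chilling temperature implied by a parameter set.
#'
#' @param params a [phenoflex_params()] object.
#' @param temps temperature grid, degrees C.
#' @param hours exposure duration for the chill curve (hours).
#' @return data frame with `temp_C` and `chill_portions` (or `gdh`).
#' @export
chill_response_curve <- function(params, temps = seq(0, 20, by = 0.1),
                                 hours = 1200) {
  params <- as_phenoflex_params(params)
  cp <- vapply(temps, function(tt) {
    y <- pf_chill_traj_cpp(rep(tt, hours), params[["E0"]], params[["E1"]],
                           params[["A0"]], params[["A1"]], params[["Tf"]],
                           params[["slope"]])
    y[hours]
  }, numeric(1))
  data.frame(temp_C = temps, chill_portions = cp)
}

#' @rdname chill_response_curve
#' @export
heat_response_curve <- function(params, temps = seq(0, 40, by = 0.1)) {
  data.frame(temp_C = temps, gdh = gdh_value(temps, params))
}
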