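#' Day length from latitude and day of year
#'
#' Forsythe et al.'s CBM day-length model: solar declination from a truncated
#' Fourier expansion of the Earth's orbital position, then the half-day arc at
#' the given latitude. Sunrise and sunset are expressed in local solar hours
#' symmetric about noon.
#'
#' @param latitude degrees N (negative for S). Absolute values of 66.6 or more
#'   (polar day/night) are not supported.
#' @param day_of_year 1--366. Vectorized together with `latitude`.
#' @return data frame with `sunrise`, `sunset` and `daylength` in hours.
#' @export
#' @examples
#' day_length(51.5, 172) # midsummer in southern Britain, about 16.4 h
day_length <- function(latitude, day_of_year) {
  if (any(abs(latitude) >= 66.6))
    stop("polar latitudes (|latitude| >= 66.6) are not supported")
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (day_of_year - 186)))
  phi <- asin(0.39795 * cos(theta)) # solar declination, radians
  latr <- latitude * pi / 180
  arg <- (sin(latr) * sin(phi)) / (cos(latr) * cos(phi))
  D <- 24 - (24 / pi) * acos(pmin(1, pmax(-1, arg)))
  data.frame(sunrise = 12 - D / 2, sunset = 12 + D / 2, daylength = D)
}

#' Downscale daily Tmin/Tmax to an idealized hourly series
#'
#' Daytime temperatures follow a sine from the daily minimum at sunrise,
#' peaking `(daylength + 4) / 2` hours after sunrise (the stretched sine of
#' Linvill-type diurnal curves): `T(h) = tmin + (tmax - tmin)
#' sin(pi (h - sunrise) / (daylength + 4))`. After sunset the temperature
#' declines logarithmically from the sunset temperature to the next day's
#' minimum at the next sunrise. Hours are local civil hours 0--23 treated as
#' instantaneous values; no daylight-saving adjustment is applied.
#'
#' @param daily data frame with columns `date` (Date), `tmin`, `tmax`
#'   (degrees C). Dates must be consecutive; gaps of at most `max_gap` days
#'   are filled by linear interpolation of `tmin`/`tmax`, longer gaps are an
#'   error.
#' @param latitude latitude of the site/cell, degrees N.
#' @param max_gap largest internal gap (days) to fill by interpolation.
#' @return data frame with columns `date`, `hour` (0--23) and `temp`, with the
#'   latitude stored as an attribute.
#' @export
daily_to_hourly <- function(daily, latitude, max_gap = 0) {
  stopifnot(all(c("date", "tmin", "tmax") %in% names(daily)))
  daily <- daily[order(daily$date), , drop = FALSE]
  if (nrow(daily) < 2)
    stop("need at least 2 consecutive days (night segments use the next day)")
  gaps <- as.numeric(diff(daily$date)) - 1
  if (any(gaps > 0)) {
    if (max(gaps) > max_gap)
      stop(sprintf("temperature series has a %d-day gap (max_gap = %d)",
                   max(gaps), max_gap))
    full <- data.frame(date = seq(min(daily$date), max(daily$date), by = "day"))
    full$tmin <- approx(daily$date, daily$tmin, xout = full$date)$y
    full$tmax <- approx(daily$date, daily$tmax, xout = full$date)$y
    message(sprintf("filled %d missing day(s) by linear interpolation",
                    nrow(full) - nrow(daily)))
    daily <- full
  }
  if (any(daily$tmax < daily$tmin))
    stop("tmax < tmin on ", sum(daily$tmax < daily$tmin), " day(s)")

  n <- nrow(daily)
  doy <- as.integer(format(daily$date, "%j"))
  dl <- day_length(latitude, doy)
  sr <- dl$sunrise; ss <- dl$sunset; L <- dl$daylength
  tmin <- daily$tmin; tmax <- daily$tmax
  tsunset <- tmin + (tmax - tmin) * sin(pi * L / (L + 4))
  # next / previous day quantities (end days reuse their own values)
  sr_next <- c(sr[-1], sr[n])
  tmin_next <- c(tmin[-1], tmin[n])
  ss_prev <- c(ss[1], ss[-n])
  tsunset_prev <- c(tsunset[1], tsunset[-n])
  nightlen <- sr_next + 24 - ss

  di <- rep(seq_len(n), each = 24)
  h <- rep(0:23, times = n)
  SR <- sr[di]; SS <- ss[di]; LL <- L[di]
  day_t <- tmin[di] + (tmax[di] - tmin[di]) * sin(pi * (h - SR) / (LL + 4))
  night_t <- tsunset[di] - (tsunset[di] - tmin_next[di]) *
    log1p(pmax(0, h - SS)) / log1p(nightlen[di])
  nl_prev <- SR + 24 - ss_prev[di]
  pre_t <- tsunset_prev[di] - (tsunset_prev[di] - tmin[di]) *
    log1p(pmax(0, h + 24 - ss_prev[di])) / log1p(nl_prev)
  temp <- ifelse(h < SR, pre_t, ifelse(h <= SS, day_t, night_t))
  temp[di == 1 & h < SR] <- tmin[1] # first day has no preceding sunset

  out <- data.frame(date = daily$date[di], hour = h, temp = temp)
  attr(out, "latitude") <- latitude
  out
}
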