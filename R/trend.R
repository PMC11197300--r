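#' Latitudinal trend in flowering onset
#'
#' Ordinary least squares of onset day of year on latitude, fitted separately
#' per cultivar, with a two-sided t test on the slope. The slope estimates
#' how many days later flowering starts per degree of latitude further north.
#'
#' @param observations data frame with `cultivar`, `latitude`, `onset_doy`
#'   (per-cell mean onset values from [aggregate_by_cell()], or raw records
#'   with those columns).
#' @return data frame with one row per cultivar: `cultivar`, `estimate`
#'   (days per degree latitude), `se`, `statistic`, `p_value`, `n`.
#' @export
fit_latitude_trend <- function(observations) {
  out <- lapply(split(observations, observations$cultivar), function(d) {
    if (nrow(d) < 3 || length(unique(d$latitude)) < 2)
      stop("need at least 3 observations with distinct latitudes (cultivar ",
           d$cultivar[1], ")")
    m <- lm(onset_doy ~ latitude, data = d)
    cf <- summary(m)$coefficients
    data.frame(cultivar = d$cultivar[1], estimate = cf["latitude", 1],
               se = cf["latitude", 2], statistic = cf["latitude", 3],
               p_value = cf["latitude", 4], n = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Benjamini--Hochberg correction
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#' Adjusted p-values are never smaller than the raw ones and preserve their
#' ordering; rejections are taken at level `q`.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return data frame with `p`, `p_adjusted`, `rejected`.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = adj, rejected = adj <= q)
}

#' Per-cultivar latitude trend table with FDR correction
#'
#' Combines [fit_latitude_trend()] and [benjamini_hochberg()] into the
#' standard reporting table.
#'
#' @inheritParams fit_latitude_trend
#' @param q FDR level for the correction.
#' @return trend data frame with added `p_corrected` and `significant`
#'   columns.
#' @export
latitude_trend_table <- function(observations, q = 0.05) {
  tab <- fit_latitude_trend(observations)
  bh <- benjamini_hochberg(tab$p_value, q)
  tab$p_corrected <- bh$p_adjusted
  tab$significant <- bh$rejected
  tab
}
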