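#' Predict flowering onset for a grid of cells
#'
#' Runs the fitted model over every cell's hourly series. With a bootstrap
#' ensemble, per-cell uncertainty is summarized as the standard deviation and
#' the 16th/84th percentiles of the replicate predictions. Cells that never
#' reach the heat requirement are flagged (`NA` onset) and excluded from
#' classification. Map classes are Jenks natural breaks on the best
#' predictions.
#'
#' @param cells data frame with `cell_id`, `latitude`, `longitude`.
#' @param temps named list (by `cell_id`) of hourly series.
#' @param fit a `"phenoflex_fit"` (or any [phenoflex_params()] via
#'   `as_phenoflex_params`, in which case a default [fit_config()] season is
#'   used).
#' @param ensemble optional `"bootstrap_ensemble"`.
#' @param classes number of Jenks map classes (default 5).
#' @param season_start passed to the engine.
#' @return data frame with `cell_id`, `latitude`, `longitude`, `onset_doy`,
#'   `bloomed` and, with an ensemble, `sd`, `p16`, `p84`; `class` holds the
#'   Jenks class index (`NA` for no-bloom cells).
#' @export
predict_grid <- function(cells, temps, fit, ensemble = NULL, classes = 5,
                         season_start = NULL) {
  if (inherits(fit, "phenoflex_fit")) {
    cfg <- fit$cfg
    if (!is.null(season_start)) cfg$season_start <- season_start
    par <- fit$par
  } else {
    par <- as_phenoflex_params(fit)
    cfg <- fit_config(start = par,
                      lower = pmin(phenoflex_bounds()$lower, unclass(par)),
                      upper = pmax(phenoflex_bounds()$upper, unclass(par)),
                      season_start = season_start)
  }
  missing <- setdiff(cells$cell_id, names(temps))
  if (length(missing) > 0) {
    warning("no temperatures for ", length(missing),
            " cell(s); they are skipped: ",
            paste(head(missing, 5), collapse = ", "))
    cells <- cells[cells$cell_id %in% names(temps), , drop = FALSE]
  }
  predictor <- make_predictor(cells$cell_id, temps, cfg)
  best <- predictor(unclass(par))
  out <- data.frame(cell_id = cells$cell_id, latitude = cells$latitude,
                    longitude = cells$longitude, onset_doy = best,
                    bloomed = !is.na(best))
  if (!is.null(ensemble)) {
    reps <- apply(ensemble$params, 1,
                  function(p) predictor(stats::setNames(p, .pf_par_names)))
    reps <- matrix(reps, ncol = nrow(ensemble$params))
    out$sd <- apply(reps, 1, function(v) sd(v, na.rm = TRUE))
    out$p16 <- apply(reps, 1, function(v) bw_quantile(v, 0.16))
    out$p84 <- apply(reps, 1, function(v) bw_quantile(v, 0.84))
  }
  out$class <- NA_integer_
  ok <- !is.na(out$onset_doy)
  if (sum(ok) >= 1) {
    k <- min(classes, length(unique(out$onset_doy[ok])))
    breaks <- jenks_breaks(out$onset_doy[ok], k)
    out$class[ok] <- jenks_classify(out$onset_doy[ok], breaks)
  }
  out
}

#' Flowering onset period
#'
#' The central onset window across predicted cells: the 25th to 75th
#' percentile of the predicted onset days (linear-interpolation quantiles).
#' No-bloom cells are excluded.
#'
#' @param predictions output of [predict_grid()] or a numeric vector of
#'   day-of-year values.
#' @param year optional calendar year used to convert the bounds to dates.
#' @return list with `start_doy`, `end_doy` and, when `year` is given,
#'   `start_date`, `end_date`.
#' @export
onset_period <- function(predictions, year = NULL) {
  doy <- if (is.data.frame(predictions)) predictions$onset_doy else predictions
  doy <- doy[!is.na(doy)]
  if (length(doy) == 0) stop("no bloom predictions to summarize")
  q <- bw_quantile(doy, c(0.25, 0.75))
  out <- list(start_doy = q[1], end_doy = q[2])
  if (!is.null(year)) {
    jan1 <- as.Date(sprintf("%d-01-01", year))
    out$start_date <- jan1 + round(q[1]) - 1
    out$end_date <- jan1 + round(q[2]) - 1
  }
  out
}

#' Jenks natural breaks (Fisher optimal 1-D partition)
#'
#' Finds the `k`-class partition of sorted values minimizing the total
#' within-class sum of squared deviations, by dynamic programming over class
#' boundaries. Deterministic; ties are broken toward the earlier break.
#'
#' @param values numeric vector (`n >= k`).
#' @param k number of classes (>= 1).
#' @return numeric vector of length `k`: the upper boundary (maximum value)
#'   of each class, with the total within-class sum of squares attached as
#'   attribute `"wss"`.
#' @export
jenks_breaks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k must not exceed the number of values")
  s1 <- cumsum(x)
  s2 <- cumsum(x^2)
  css <- function(i, j) { # within-class SS of x[i..j]
    s <- s2[j] - if (i > 1) s2[i - 1] else 0
    m <- s1[j] - if (i > 1) s1[i - 1] else 0
    s - m^2 / (j - i + 1)
  }
  D <- matrix(Inf, n, k)     # D[j, m]: best cost of x[1..j] in m classes
  B <- matrix(0L, n, k)      # start index of the last class
  for (j in 1:n) {
    D[j, 1] <- css(1, j)
    B[j, 1] <- 1L
  }
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        for (i in m:j) {
          v <- D[i - 1, m - 1] + css(i, j)
          if (v < D[j, m] - 1e-12) { # strict: earliest cut wins on ties
            D[j, m] <- v
            B[j, m] <- i
          }
        }
      }
    }
  }
  ends <- integer(k)
  j <- n
  for (m in k:1) {
    ends[m] <- j
    j <- B[j, m] - 1L
  }
  breaks <- x[ends]
  attr(breaks, "wss") <- D[n, k]
  breaks
}

#' @param breaks output of `jenks_breaks`.
#' @rdname jenks_breaks
#' @return `jenks_classify`: integer class index (1 = earliest class) per
#'   value.
#' @export
jenks_classify <- function(values, breaks) {
  vapply(values, function(v) {
    cl <- which(v <= breaks + 1e-9)
    if (length(cl) == 0) length(breaks) else cl[1]
  }, integer(1))
}

#' Compare yearly predictions with a standardized reference series
#'
#' Joins predictions and reference observations by year and reports the mean
#' signed difference in days (positive = prediction later than the
#' reference), the convention used when benchmarking against long-term
#' single-site phenology collections.
#'
#' @param predicted data frame with `year` and `doy`.
#' @param reference data frame with `year` and `doy`.
#' @return list with `mean_difference` (days) and a per-year `table`
#'   (`year`, `predicted`, `observed`, `difference`).
#' @export
compare_reference <- function(predicted, reference) {
  m <- merge(predicted, reference, by = "year", suffixes = c("_pred", "_obs"))
  if (nrow(m) == 0) stop("no overlapping years")
  tab <- data.frame(year = m$year, predicted = m$doy_pred,
                    observed = m$doy_obs,
                    difference = m$doy_pred - m$doy_obs)
  list(mean_difference = mean(tab$difference), table = tab)
}
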