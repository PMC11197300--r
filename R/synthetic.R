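#' Configuration for the synthetic gridded climate
#'
#' The generator emulates the structure of a gridded daily Tmin/Tmax extract
#' over Great Britain: a south--north mean-temperature gradient, a seasonal
#' cycle, a fixed diurnal range and AR(1) day-to-day weather noise. The daily
#' mean at latitude `lat` and day of year `d` is
#' `base_temp + lapse (lat - lat_ref) + amplitude cos(2 pi (d - warmest_day) /
#' 365.25)` plus AR(1) noise; `tmin`/`tmax` sit half the diurnal range below
#' and above it.
#'
#' @param start,end first and last day of the series. The default window
#'   spans one full dormancy-to-bloom season (autumn chill through summer).
#' @param lat_range latitudes (degrees N) the generated grid is meant to
#'   cover; cells outside it trigger a warning.
#' @param base_temp mean annual temperature at `lat_ref`, degrees C.
#' @param lat_ref reference latitude for `base_temp`.
#' @param lapse change in mean temperature per degree latitude (degrees C).
#' @param amplitude seasonal half-range of the daily mean, degrees C.
#' @param warmest_day day of year of the seasonal maximum.
#' @param diurnal_range tmax minus tmin, degrees C (>= 0).
#' @param ar1 AR(1) coefficient of the daily noise, in `[0, 1)`.
#' @param noise_sd innovation standard deviation of the noise, degrees C.
#' @param seed integer seed; all generator output is deterministic given it.
#' @return list of class `"climate_config"`.
#' @export
climate_config <- function(start = as.Date("2021-08-01"),
                           end = as.Date("2022-06-30"),
                           lat_range = c(50, 58), base_temp = 10,
                           lat_ref = 51, lapse = -0.5, amplitude = 5.5,
                           warmest_day = 200, diurnal_range = 7,
                           ar1 = 0.7, noise_sd = 1.2, seed = 42) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("degenerate date range: end must be after start")
  if (as.numeric(end - start) < 300)
    warning("date range shorter than a full dormancy-to-bloom season")
  if (diurnal_range < 0) stop("diurnal_range must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)")
  structure(list(start = start, end = end, lat_range = lat_range,
                 base_temp = base_temp, lat_ref = lat_ref, lapse = lapse,
                 amplitude = amplitude, warmest_day = warmest_day,
                 diurnal_range = diurnal_range, ar1 = ar1,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "climate_config")
}

#' Configuration for synthetic citizen-science observations
#'
#' Controls how noisy submission records are derived from true bloom dates.
#' Onset-stage records (codes A and B) are dated at the true onset plus
#' Gaussian noise rounded to whole days; later stages are shifted by a
#' stage-specific window first. A configured fraction of records lack photos,
#' and a configured fraction are gross outliers displaced by a large offset.
#'
#' @param records_per_cell number of records generated per blooming cell.
#' @param noise_sd SD (days) of the Gaussian observation noise on dates.
#' @param outlier_rate fraction of records turned into gross outliers.
#' @param outlier_offset absolute displacement (days) of a gross outlier;
#'   sign is random.
#' @param missing_photo_rate fraction of records submitted without photos.
#' @param stage_probs sampling probabilities of the five stage codes A--E.
#' @param stage_windows named list of integer day ranges (relative to the
#'   true onset) in which each stage code is recorded. Onset codes default to
#'   the true date itself; mid and late flowering default to +7 +/- 2 and
#'   +14 +/- 3 days.
#' @param independent_rate fraction of records that also carry an independent
#'   re-verified stage code (equal to the recorded one).
#' @param seed integer seed.
#' @return list of class `"observation_config"`.
#' @export
observation_config <- function(records_per_cell = 1, noise_sd = 1,
                               outlier_rate = 0, outlier_offset = 60,
                               missing_photo_rate = 0,
                               stage_probs = c(A = 0.30, B = 0.25, C = 0.20,
                                               D = 0.15, E = 0.10),
                               stage_windows = list(A = c(0, 0), B = c(0, 0),
                                                    C = c(5, 9),
                                                    D = c(11, 17),
                                                    E = c(11, 17)),
                               independent_rate = 0, seed = 42) {
  rates <- c(outlier_rate, missing_photo_rate, independent_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(records_per_cell >= 1,
            all(c("A", "B", "C", "D", "E") %in% names(stage_probs)),
            all(c("A", "B", "C", "D", "E") %in% names(stage_windows)))
  structure(list(records_per_cell = as.integer(records_per_cell),
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 outlier_offset = outlier_offset,
                 missing_photo_rate = missing_photo_rate,
                 stage_probs = stage_probs / sum(stage_probs),
                 stage_windows = stage_windows,
                 independent_rate = independent_rate,
                 seed = as.integer(seed)),
            class = "observation_config")
}

#' Build a list of 0.1-degree grid cells
#'
#' Helper for tests and simulations: `n` distinct cells with centers snapped
#' to the 0.1-degree grid, spanning `lat_range` south to north.
#'
#' @param n number of cells.
#' @param lat_range range of latitudes to span.
#' @param lon longitude(s) of the cells (recycled).
#' @return data frame with `cell_id`, `latitude`, `longitude` (cell centers).
#' @export
synthetic_cells <- function(n, lat_range = c(50.0, 58.0), lon = -1.05) {
  ilat_all <- seq(floor(lat_range[1] * 10), ceiling(lat_range[2] * 10) - 1)
  n_lon <- ceiling(n / length(ilat_all))
  grid <- expand.grid(ilon = round(lon[1] * 10) + seq_len(n_lon) - 1,
                      ilat = ilat_all)
  idx <- unique(round(seq(1, nrow(grid), length.out = min(n, nrow(grid)))))
  grid <- grid[sort(idx), , drop = FALSE]
  lat <- grid$ilat / 10 + 0.05
  lonc <- grid$ilon / 10 + 0.05
  data.frame(cell_id = grid_cell_id(lat, lonc), latitude = lat,
             longitude = lonc)
}

#' Generate daily gridded temperatures
#'
#' One daily Tmin/Tmax series per grid cell under a [climate_config()].
#' Noise is drawn independently per cell but deterministically given the
#' seed and the cell order.
#'
#' @param cells data frame with `cell_id`, `latitude`, `longitude`.
#' @param cfg a [climate_config()].
#' @return named list (by `cell_id`) of data frames with `date`, `tmin`,
#'   `tmax`; the configuration is attached as an attribute.
#' @export
gen_daily_temps <- function(cells, cfg = climate_config()) {
  stopifnot(inherits(cfg, "climate_config"))
  if (nrow(cells) == 0) stop("empty cell list")
  if (anyDuplicated(cells$cell_id)) stop("cells must have distinct centers")
  if (any(cells$latitude < cfg$lat_range[1] - 0.1 |
          cells$latitude > cfg$lat_range[2] + 0.1))
    warning("some cells lie outside the configured latitude range")
  dates <- seq(cfg$start, cfg$end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cfg$amplitude * cos(2 * pi * (doy - cfg$warmest_day) / 365.25)
  nd <- length(dates)
  out <- with_seed(cfg$seed, {
    lapply(seq_len(nrow(cells)), function(i) {
      mu <- cfg$base_temp + cfg$lapse * (cells$latitude[i] - cfg$lat_ref) +
        seasonal
      eps <- numeric(nd)
      if (cfg$noise_sd > 0) {
        innov <- rnorm(nd, sd = cfg$noise_sd)
        eps[1] <- innov[1]
        for (t in seq_len(nd - 1))
          eps[t + 1] <- cfg$ar1 * eps[t] + innov[t + 1]
      }
      tmean <- mu + eps
      data.frame(date = dates, tmin = tmean - cfg$diurnal_range / 2,
                 tmax = tmean + cfg$diurnal_range / 2)
    })
  })
  names(out) <- cells$cell_id
  attr(out, "config") <- cfg
  out
}

#' True bloom dates under known parameters
#'
#' Runs the forward kinetic model for every cell on its downscaled hourly
#' series, producing the ground-truth onset day of year each cell would show
#' under the supplied parameters. Cells whose heat requirement is never met
#' carry `NA` as an explicit no-bloom sentinel.
#'
#' @param cells data frame with `cell_id`, `latitude`, `longitude`.
#' @param daily named list of daily series from [gen_daily_temps()].
#' @param params a [phenoflex_params()] object (the "true" parameters).
#' @param season_start passed to [predict_bloom()].
#' @param max_gap largest temperature gap (days) tolerated, see
#'   [daily_to_hourly()].
#' @return data frame `cell_id`, `latitude`, `longitude`, `true_doy` with the
#'   bloom year attached as attribute `"bloom_year"`.
#' @export
gen_truth <- function(cells, daily, params, season_start = NULL, max_gap = 0) {
  params <- as_phenoflex_params(params)
  stopifnot(all(cells$cell_id %in% names(daily)))
  preds <- lapply(seq_len(nrow(cells)), function(i) {
    hourly <- daily_to_hourly(daily[[cells$cell_id[i]]], cells$latitude[i],
                              max_gap = max_gap)
    predict_bloom(hourly, params, season_start = season_start)
  })
  out <- data.frame(cell_id = cells$cell_id, latitude = cells$latitude,
                    longitude = cells$longitude,
                    true_doy = vapply(preds, function(p) p$bloom_doy,
                                      numeric(1)))
  attr(out, "bloom_year") <- preds[[1]]$bloom_year
  out
}

#' Generate noisy citizen-science-like records
#'
#' Derives submission records from true bloom dates under an
#' [observation_config()]: stage codes sampled from `stage_probs`, record
#' dates at the true onset plus the stage window plus rounded Gaussian noise,
#' a configured fraction of photo-less records and of gross outliers.
#' Coordinates are jittered within the cell and rounded to 5 decimals so the
#' records CSV round-trips losslessly. Cells with the no-bloom sentinel yield
#' no records.
#'
#' @param truth output of [gen_truth()].
#' @param cfg an [observation_config()].
#' @param tree_type,cultivar labels stamped on every record.
#' @return data frame of phenology records (see [read_records_csv()] for the
#'   schema).
#' @export
gen_records <- function(truth, cfg = observation_config(), tree_type = "plum",
                        cultivar = "Victoria") {
  stopifnot(inherits(cfg, "observation_config"))
  bloom_year <- attr(truth, "bloom_year")
  if (is.null(bloom_year))
    bloom_year <- 1900 + as.POSIXlt(Sys.Date())$year # fallback, labelled year
  truth <- truth[!is.na(truth$true_doy), , drop = FALSE]
  if (nrow(truth) == 0) stop("truth is empty (or all cells failed to bloom)")
  jan1 <- as.Date(sprintf("%d-01-01", bloom_year))
  stages <- names(cfg$stage_probs)
  with_seed(cfg$seed, {
    n <- nrow(truth) * cfg$records_per_cell
    ci <- rep(seq_len(nrow(truth)), each = cfg$records_per_cell)
    stage <- sample(stages, n, replace = TRUE, prob = cfg$stage_probs)
    win <- vapply(stage, function(s) {
      w <- cfg$stage_windows[[s]]
      if (w[1] == w[2]) w[1] else sample(seq(w[1], w[2]), 1)
    }, numeric(1))
    noise <- if (cfg$noise_sd > 0) round(rnorm(n, sd = cfg$noise_sd)) else
      rep(0, n)
    outlier <- runif(n) < cfg$outlier_rate
    shift <- ifelse(outlier,
                    cfg$outlier_offset * sample(c(-1, 1), n, replace = TRUE),
                    0)
    doy <- truth$true_doy[ci] + win + noise + shift
    has_photos <- runif(n) >= cfg$missing_photo_rate
    indep <- ifelse(runif(n) < cfg$independent_rate, stage, NA_character_)
    data.frame(
      record_id = seq_len(n),
      date = jan1 + doy - 1,
      latitude = round(truth$latitude[ci] + runif(n, -0.049, 0.049), 5),
      longitude = round(truth$longitude[ci] + runif(n, -0.049, 0.049), 5),
      tree_type = tree_type,
      cultivar = cultivar,
      stage_code = stage,
      has_photos = has_photos,
      independent_stage_code = indep,
      image_usable = TRUE,
      stringsAsFactors = FALSE
    )
  })
}

#' Read/write phenology records CSV
#'
#' Schema: `record_id`, `date` (ISO-8601), `latitude`, `longitude`,
#' `tree_type`, `cultivar`, `stage_code` (A--E), `has_photos` (logical),
#' `independent_stage_code` (optional A--E), `image_usable` (logical).
#'
#' @param records data frame of phenology records.
#' @param path file path.
#' @return `read_records_csv` returns the records data frame.
#' @export
write_records_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(date = "Date"), na.strings = "")
  out$has_photos <- as.logical(out$has_photos)
  if ("image_usable" %in% names(out))
    out$image_usable <- as.logical(out$image_usable)
  else
    out$image_usable <- TRUE
  if (!"independent_stage_code" %in% names(out))
    out$independent_stage_code <- NA_character_
  out
}

#' Write daily cell series as a long CSV
#'
#' Columns: `cell_id`, `date`, `tmin`, `tmax`.
#'
#' @param daily named list of daily series from [gen_daily_temps()].
#' @param path file path.
#' @export
write_daily_csv <- function(daily, path) {
  long <- do.call(rbind, lapply(names(daily), function(id)
    cbind(cell_id = id, daily[[id]])))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_daily_csv
#' @export
read_daily_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(date = "Date"))
  split(long[c("date", "tmin", "tmax")], long$cell_id)
}
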