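#' Grid-cell assignment on the 0.1-degree grid
#'
#' A record at (lat, lon) belongs to the cell with index
#' `floor(lat / 0.1), floor(lon / 0.1)`; the cell center sits at
#' `index * 0.1 + 0.05`.
#'
#' @param latitude,longitude WGS84 decimal degrees. Vectorized.
#' @return `grid_cell_id`: character ids; `grid_cell_center`: data frame with
#'   the center coordinates of each id.
#' @export
grid_cell_id <- function(latitude, longitude) {
  ilat <- floor(latitude * 10 + 1e-7)
  ilon <- floor(longitude * 10 + 1e-7)
  sprintf("%d_%d", ilat, ilon)
}

#' @param cell_id ids produced by `grid_cell_id`.
#' @rdname grid_cell_id
#' @export
grid_cell_center <- function(cell_id) {
  parts <- strsplit(cell_id, "_", fixed = TRUE)
  ilat <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  ilon <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  data.frame(cell_id = cell_id, latitude = ilat / 10 + 0.05,
             longitude = ilon / 10 + 0.05)
}

# Great Britain bounding box used for the out-of-area check.
.gb_lat <- c(49, 61)
.gb_lon <- c(-8.5, 2)

#' Quality-control filter for submitted records
#'
#' Applies, in order, the standard cleaning rules for opportunistic flowering
#' records, logging every removal with its reason:
#' \enumerate{
#'   \item records without photographs (stage cannot be verified);
#'   \item records dated on a media-spike date (a publicity burst that skews
#'     the date distribution; default 2022-03-19);
#'   \item records whose images are unusable;
#'   \item records outside Great Britain or with unmappable locations.
#' }
#'
#' @param records phenology records data frame.
#' @param spike_dates dates to drop wholesale.
#' @return list with `kept` (the surviving records) and `log` (data frame
#'   `record_id`, `rule`).
#' @export
filter_records <- function(records, spike_dates = as.Date("2022-03-19")) {
  log <- data.frame(record_id = integer(0), rule = character(0))
  drop <- function(mask, rule) {
    if (any(mask)) {
      log <<- rbind(log, data.frame(record_id = records$record_id[mask],
                                    rule = rule))
      records <<- records[!mask, , drop = FALSE]
    }
  }
  if (!"image_usable" %in% names(records)) records$image_usable <- TRUE
  drop(!records$has_photos, "no_photo")
  drop(records$date %in% spike_dates, "media_spike_date")
  drop(!records$image_usable, "unusable_image")
  out_of_area <- is.na(records$latitude) | is.na(records$longitude) |
    records$latitude < .gb_lat[1] | records$latitude > .gb_lat[2] |
    records$longitude < .gb_lon[1] | records$longitude > .gb_lon[2]
  drop(out_of_area, "out_of_area")
  list(kept = records, log = log)
}

#' Reclassify five stage codes into three flowering phases
#'
#' Observers disagree most between adjacent stage codes, so the five-level
#' coding (A = first flowers open, BBCH 60; B = 10% open, 61; C = 50% open,
#' 65; D = fading, 67; E = end, 69) is coarsened to Start (A, B), Full (C)
#' and End (D, E).
#'
#' @param stage_code character vector of codes A--E.
#' @return character vector of `"Start"`, `"Full"`, `"End"`.
#' @export
reclassify_stage <- function(stage_code) {
  map <- c(A = "Start", B = "Start", C = "Full", D = "End", E = "End")
  bad <- !stage_code %in% names(map)
  if (any(bad))
    stop("unknown stage code(s): ", paste(unique(stage_code[bad]),
                                          collapse = ", "))
  unname(map[stage_code])
}

#' Agreement between original and independently verified stage codes
#'
#' For records that were re-verified from their photographs, tabulates the
#' percentage classified identically, differing by exactly one stage on the
#' A < B < C < D < E ordering, differing by more than one stage, and with
#' unusable images (missing independent code). The same summary is computed
#' after coarsening to the three-level Start/Full/End scheme, where agreement
#' can only increase.
#'
#' @param original,independent character vectors of stage codes (A--E);
#'   `NA` in `independent` marks an unusable image.
#' @return list with data frames `five_level` and `three_level`
#'   (`category`, `percent`); percentages sum to 100.
#' @export
consensus_stats <- function(original, independent) {
  stopifnot(length(original) == length(independent))
  n <- length(original)
  if (n == 0) stop("no pairs supplied")
  unusable <- is.na(independent)
  rank5 <- c(A = 1, B = 2, C = 3, D = 4, E = 5)
  d5 <- abs(rank5[original] - rank5[independent])
  tab5 <- c(same = sum(d5 == 0, na.rm = TRUE),
            off_by_one = sum(d5 == 1, na.rm = TRUE),
            off_by_more = sum(d5 > 1, na.rm = TRUE),
            unusable = sum(unusable))
  rank3 <- c(Start = 1, Full = 2, End = 3)
  d3 <- abs(rank3[reclassify_stage(original)] -
              rank3[ifelse(unusable, "A", independent) |>
                      reclassify_stage()])
  d3[unusable] <- NA
  tab3 <- c(same = sum(d3 == 0, na.rm = TRUE),
            off_by_one = sum(d3 == 1, na.rm = TRUE),
            off_by_more = sum(d3 > 1, na.rm = TRUE),
            unusable = sum(unusable))
  as_pct <- function(tab) data.frame(category = names(tab),
                                     percent = 100 * as.numeric(tab) / n)
  list(five_level = as_pct(tab5), three_level = as_pct(tab3))
}

#' Select flowering-onset records for a cultivar
#'
#' Onset is defined as the earliest flowering stages (codes A and B, BBCH 60
#' and 61 -- fewer than 10% of flowers open).
#'
#' @param records cleaned phenology records.
#' @param cultivar cultivar name to keep; `NULL` keeps all cultivars.
#' @return the onset-stage subset of `records`.
#' @export
select_onset <- function(records, cultivar = NULL) {
  keep <- records$stage_code %in% c("A", "B")
  if (!is.null(cultivar)) keep <- keep & records$cultivar == cultivar
  records[keep, , drop = FALSE]
}

#' Interquartile-range outlier filter
#'
#' Removes values below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with Q1/Q3
#' computed by linear interpolation between order statistics. Intended to be
#' applied within each cultivar-by-stage group. With fewer than 4 values the
#' fences are not meaningful and the input passes through unchanged.
#'
#' @param values numeric vector (e.g. day-of-year values).
#' @return list with `kept`, `removed` (values), `kept_idx`, `removed_idx`
#'   (indices into `values`) and the `fences` used (`NULL` when passed
#'   through).
#' @export
iqr_filter <- function(values) {
  if (length(values) < 4) {
    return(list(kept = values, removed = numeric(0),
                kept_idx = seq_along(values), removed_idx = integer(0),
                fences = NULL, passed_through = TRUE))
  }
  q <- bw_quantile(values, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  out <- values < fences[1] | values > fences[2]
  list(kept = values[!out], removed = values[out],
       kept_idx = which(!out), removed_idx = which(out),
       fences = fences, passed_through = FALSE)
}

#' Full record-cleaning pipeline
#'
#' [filter_records()] followed by the IQR outlier filter applied to record
#' day-of-year within each cultivar-by-phase (Start/Full/End) group. The IQR
#' stage is iterated to a fixpoint (removing an outlier shifts the quartiles,
#' which can expose further outliers), which makes the whole pipeline
#' idempotent: cleaning an already-clean table changes nothing.
#'
#' @param records phenology records.
#' @param spike_dates passed to [filter_records()].
#' @param iqr apply the IQR outlier stage.
#' @return list with `kept` and `log` (`record_id`, `rule`).
#' @export
clean_records <- function(records, spike_dates = as.Date("2022-03-19"),
                          iqr = TRUE) {
  step1 <- filter_records(records, spike_dates)
  kept <- step1$kept
  log <- step1$log
  while (iqr && nrow(kept) > 0) {
    doy <- as.integer(format(kept$date, "%j"))
    grp <- paste(kept$cultivar, reclassify_stage(kept$stage_code), sep = "|")
    out_idx <- integer(0)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      res <- iqr_filter(doy[idx])
      out_idx <- c(out_idx, idx[res$removed_idx])
    }
    if (length(out_idx) == 0) break
    log <- rbind(log, data.frame(record_id = kept$record_id[out_idx],
                                 rule = "iqr_outlier"))
    kept <- kept[-out_idx, , drop = FALSE]
  }
  list(kept = kept, log = log)
}

#' Aggregate onset records onto the 0.1-degree grid
#'
#' Each record is assigned to its grid cell; where several records of a
#' cultivar fall in one cell, their mean flowering day of year is used
#' (kept fractional for model fitting). Latitude/longitude are the cell
#' center.
#'
#' @param records onset-stage records (see [select_onset()]).
#' @return data frame with `cell_id`, `latitude`, `longitude`, `cultivar`,
#'   `onset_doy`, `n` -- one row per cultivar-by-cell combination.
#' @export
aggregate_by_cell <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(cell_id = character(0), latitude = numeric(0),
                      longitude = numeric(0), cultivar = character(0),
                      onset_doy = numeric(0), n = integer(0)))
  doy <- as.integer(format(records$date, "%j"))
  cid <- grid_cell_id(records$latitude, records$longitude)
  key <- paste(records$cultivar, cid, sep = "|")
  agg <- tapply(doy, key, mean)
  nrec <- tapply(doy, key, length)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  cultivar <- vapply(parts, `[`, "", 1)
  cell_id <- vapply(parts, `[`, "", 2)
  centers <- grid_cell_center(cell_id)
  out <- data.frame(cell_id = cell_id, latitude = centers$latitude,
                    longitude = centers$longitude, cultivar = cultivar,
                    onset_doy = as.numeric(agg), n = as.integer(nrec))
  rownames(out) <- NULL
  out[order(out$cultivar, out$latitude, out$longitude), , drop = FALSE]
}

#' Latitude-patterned calibration/validation split
#'
#' Observations are sorted south to north and labelled in a repeating
#' `v, c, c, c` pattern (validation, calibration, calibration, calibration)
#' starting at the southernmost cell, so that both subsets span the full
#' latitude -- and hence temperature -- range. Ties in latitude are broken by
#' longitude, then by cell id. With fewer than 4 observations everything is
#' assigned to calibration, with a warning.
#'
#' @param observations data frame with at least `latitude`, `longitude`,
#'   `cell_id`.
#' @return `observations` with an added `split` column (`"calibration"` /
#'   `"validation"`), rows ordered south to north.
#' @export
split_cal_val <- function(observations) {
  n <- nrow(observations)
  ord <- order(observations$latitude, observations$longitude,
               observations$cell_id)
  out <- observations[ord, , drop = FALSE]
  if (n < 4) {
    warning("fewer than 4 observations: all assigned to calibration")
    out$split <- rep("calibration", n)
    return(out)
  }
  out$split <- rep_len(c("validation", "calibration", "calibration",
                         "calibration"), n)
  out
}
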