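# Shared fixtures built once per test run. The heavier objects (a small
# synthetic study with hourly series) are memoized in this environment so
# several test files can reuse them without regenerating.

.fixtures <- new.env(parent = emptyenv())

# A small synthetic study: cells, daily + hourly temperatures and true bloom
# dates under the plum 'Victoria' reference parameters.
small_study <- function(n_cells = 20, climate_seed = 101) {
  key <- sprintf("study_%d_%d", n_cells, climate_seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  par <- example_cultivar_params()$Victoria
  cells <- synthetic_cells(n_cells)
  daily <- gen_daily_temps(cells, climate_config(seed = climate_seed))
  truth <- gen_truth(cells, daily, par)
  temps <- lapply(seq_len(nrow(cells)), function(i)
    daily_to_hourly(daily[[cells$cell_id[i]]], cells$latitude[i]))
  names(temps) <- cells$cell_id
  out <- list(par = par, cells = cells, daily = daily, truth = truth,
              temps = temps)
  .fixtures[[key]] <- out
  out
}

# Noise-free calibration observations whose onset values equal the model's
# own continuous predictions at the generating parameters, so those
# parameters give exactly zero residuals.
exact_observations <- function(study) {
  pg <- suppressWarnings(predict_grid(study$cells, study$temps, study$par))
  obs <- data.frame(cell_id = pg$cell_id, latitude = pg$latitude,
                    longitude = pg$longitude, onset_doy = pg$onset_doy)
  obs[!is.na(obs$onset_doy), , drop = FALSE]
}

# A constant-temperature hourly series spanning a season window, for
# idealized engine tests.
constant_hourly <- function(temp_C, n_days = 60,
                            start = as.Date("2021-11-01")) {
  dates <- seq(start, by = "day", length.out = n_days)
  data.frame(date = rep(dates, each = 24), hour = rep(0:23, n_days),
             temp = temp_C)
}

# Minimal well-formed records table for the cleaning tests.
make_records <- function(n, date = as.Date("2022-04-10"), lat = 51.5,
                         lon = -1.0, stage = "A", cultivar = "Victoria",
                         has_photos = TRUE, image_usable = TRUE) {
  data.frame(record_id = seq_len(n), date = rep(date, length.out = n),
             latitude = rep(lat, length.out = n),
             longitude = rep(lon, length.out = n),
             tree_type = "plum", cultivar = rep(cultivar, length.out = n),
             stage_code = rep(stage, length.out = n),
             has_photos = rep(has_photos, length.out = n),
             independent_stage_code = NA_character_,
             image_usable = rep(image_usable, length.out = n),
             stringsAsFactors = FALSE)
}
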