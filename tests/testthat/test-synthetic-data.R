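test_that("deterministic climate field reproduces the configured gradient", {
  cells <- data.frame(cell_id = c("a", "b", "c"),
                      latitude = c(51.05, 54.05, 56.05),
                      longitude = c(-1.05, -1.05, -1.05))
  # no noise, no lapse: all cells identical
  cfg0 <- climate_config(lapse = 0, noise_sd = 0)
  d0 <- gen_daily_temps(cells, cfg0)
  expect_identical(d0[["a"]], d0[["b"]])
  expect_identical(d0[["a"]], d0[["c"]])
  # lapse -0.6: mean difference between 56.05 and 51.05 N is exactly -3
  cfg1 <- climate_config(lapse = -0.6, noise_sd = 0)
  d1 <- gen_daily_temps(cells, cfg1)
  m <- function(x) mean((x$tmin + x$tmax) / 2)
  expect_equal(m(d1[["c"]]) - m(d1[["a"]]), -3.0)
  # diurnal range and tmax >= tmin
  expect_equal(d1[["a"]]$tmax - d1[["a"]]$tmin,
               rep(cfg1$diurnal_range, nrow(d1[["a"]])))
})

test_that("generators are bit-identical under a fixed seed", {
  cells <- synthetic_cells(5)
  cfg <- climate_config(seed = 77)
  expect_identical(gen_daily_temps(cells, cfg), gen_daily_temps(cells, cfg))
  d <- gen_daily_temps(cells, climate_config(seed = 78))
  expect_false(identical(d, gen_daily_temps(cells, cfg)))
  truth <- small_study(8)$truth
  ocfg <- observation_config(records_per_cell = 2, seed = 5)
  expect_identical(gen_records(truth, ocfg), gen_records(truth, ocfg))
})

test_that("configuration invariants are enforced", {
  expect_error(climate_config(start = "2022-01-01", end = "2021-01-01"),
               "degenerate")
  expect_warning(climate_config(end = as.Date("2021-10-01")), "season")
  expect_error(climate_config(diurnal_range = -1), ">= 0")
  expect_error(climate_config(ar1 = 1), "ar1")
  expect_error(observation_config(outlier_rate = 1.2), "rates")
  expect_error(observation_config(noise_sd = -1), ">= 0")
  expect_error(gen_daily_temps(data.frame(), climate_config()), "empty")
})

test_that("forward truth follows the latitudinal temperature gradient", {
  study <- small_study(12)
  truth <- study$truth
  expect_true(all(!is.na(truth$true_doy)))
  # warmer (more southerly) cells bloom no later, allowing for weather noise
  expect_gt(cor(truth$latitude, truth$true_doy, method = "spearman"), 0.5)
  expect_lte(truth$true_doy[1], truth$true_doy[nrow(truth)])
  # identical temperatures give identical truth
  cells2 <- data.frame(cell_id = c("x", "y"), latitude = c(52.05, 52.05),
                       longitude = c(-1.05, -0.95))
  d2 <- gen_daily_temps(cells2, climate_config(noise_sd = 0))
  t2 <- gen_truth(cells2, d2, study$par)
  expect_equal(t2$true_doy[1], t2$true_doy[2])
  # unreachable heat requirement yields the no-bloom sentinel everywhere
  par_hi <- study$par
  par_hi[["zc"]] <- 1e9
  t3 <- gen_truth(cells2, d2, par_hi)
  expect_true(all(is.na(t3$true_doy)))
})

test_that("noise-free onset records equal the true bloom dates", {
  truth <- small_study(8)$truth
  cfg <- observation_config(records_per_cell = 2, noise_sd = 0,
                            outlier_rate = 0, missing_photo_rate = 0,
                            seed = 3)
  recs <- gen_records(truth, cfg)
  onset <- recs[recs$stage_code %in% c("A", "B"), ]
  doy <- as.integer(format(onset$date, "%j"))
  truth_doy <- truth$true_doy[match(grid_cell_id(onset$latitude,
                                                 onset$longitude),
                                    truth$cell_id)]
  expect_equal(doy, truth_doy)
  # later stages are shifted into their windows
  full <- recs[recs$stage_code == "C", ]
  if (nrow(full) > 0) {
    fdoy <- as.integer(format(full$date, "%j"))
    ftruth <- truth$true_doy[match(grid_cell_id(full$latitude,
                                                full$longitude),
                                   truth$cell_id)]
    expect_true(all(fdoy - ftruth >= 5 & fdoy - ftruth <= 9))
  }
})

test_that("observation noise and missingness match their configuration", {
  study <- small_study(100, climate_seed = 202)
  truth <- study$truth
  cfg <- observation_config(records_per_cell = 10, noise_sd = 2,
                            missing_photo_rate = 0.2,
                            stage_probs = c(A = 1, B = 0, C = 0, D = 0,
                                            E = 0),
                            seed = 8)
  recs <- gen_records(truth, cfg)
  expect_gte(nrow(recs), 1000)
  truth_doy <- truth$true_doy[match(grid_cell_id(recs$latitude,
                                                 recs$longitude),
                                    truth$cell_id)]
  err <- as.integer(format(recs$date, "%j")) - truth_doy
  s <- sd(err)
  expect_gt(s, 1.7) # chi-squared band for the sample SD at n = 500
  expect_lt(s, 2.3)
  # binomial 99% interval for the photo-less fraction at rate 0.2
  n_miss <- sum(!recs$has_photos)
  expect_gt(n_miss / nrow(recs), 0.16)
  expect_lt(n_miss / nrow(recs), 0.24)
})

test_that("record and daily-series tables round-trip through CSV losslessly", {
  truth <- small_study(8)$truth
  recs <- gen_records(truth, observation_config(records_per_cell = 2,
                                                noise_sd = 1,
                                                missing_photo_rate = 0.3,
                                                independent_rate = 0.5,
                                                seed = 4))
  f <- tempfile(fileext = ".csv")
  write_records_csv(recs, f)
  back <- read_records_csv(f)
  expect_equal(back, recs, ignore_attr = TRUE)
  unlink(f)
  daily <- small_study(8)$daily
  f2 <- tempfile(fileext = ".csv")
  write_daily_csv(daily, f2)
  back2 <- read_daily_csv(f2)
  for (id in names(daily))
    expect_equal(back2[[id]], daily[[id]], ignore_attr = TRUE)
  unlink(f2)
})
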