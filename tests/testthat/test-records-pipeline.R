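test_that("quality-control filter applies its rules in order and logs them", {
  recs <- make_records(3)
  recs$has_photos[1] <- FALSE
  recs$date[2] <- as.Date("2022-03-19")
  out <- filter_records(recs)
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$record_id, 3L)
  expect_setequal(out$log$rule, c("no_photo", "media_spike_date"))

  # all valid records pass through untouched
  ok <- make_records(4)
  out2 <- filter_records(ok)
  expect_equal(out2$kept, ok)
  expect_equal(nrow(out2$log), 0)

  # out-of-area and unusable-image removals
  bad <- make_records(3)
  bad$latitude[1] <- 48.0
  bad$image_usable[2] <- FALSE
  out3 <- filter_records(bad)
  expect_equal(nrow(out3$kept), 1)
  expect_true("out_of_area" %in% out3$log$rule)
  expect_true("unusable_image" %in% out3$log$rule)
})

test_that("stage codes collapse onto the three flowering phases", {
  expect_equal(reclassify_stage(c("A", "B", "C", "D", "E")),
               c("Start", "Start", "Full", "End", "End"))
  expect_error(reclassify_stage("F"), "unknown stage")
})

test_that("consensus percentages count agreement on the stage ordering", {
  # all identical
  s <- consensus_stats(rep("B", 5), rep("B", 5))
  expect_equal(s$five_level$percent[s$five_level$category == "same"], 100)
  # constructed 7 same / 2 adjacent / 1 two apart
  orig <- c(rep("A", 7), "B", "C", "A")
  indep <- c(rep("A", 7), "C", "D", "C")
  s2 <- consensus_stats(orig, indep)
  expect_equal(s2$five_level$percent, c(70, 20, 10, 0))
  expect_equal(sum(s2$five_level$percent), 100)
  expect_equal(sum(s2$three_level$percent), 100)
  # unusable images are their own category
  s3 <- consensus_stats(c("A", "B"), c("A", NA))
  expect_equal(s3$five_level$percent,  c(50, 0, 0, 50))
  expect_error(consensus_stats(character(0), character(0)), "no pairs")
})

test_that("coarsening the stage scale can only increase agreement", {
  set.seed(11)
  codes <- c("A", "B", "C", "D", "E")
  for (i in 1:20) {
    orig <- sample(codes, 40, replace = TRUE)
    indep <- sample(codes, 40, replace = TRUE)
    s <- consensus_stats(orig, indep)
    same5 <- s$five_level$percent[s$five_level$category == "same"]
    same3 <- s$three_level$percent[s$three_level$category == "same"]
    expect_gte(same3, same5)
  }
})

test_that("onset selection keeps only first-flowering stages of one cultivar", {
  recs <- make_records(4)
  recs$stage_code <- c("A", "B", "C", "D")
  expect_equal(nrow(select_onset(recs)), 2)
  recs$cultivar <- c("Victoria", "Stella", "Victoria", "Victoria")
  expect_equal(select_onset(recs, "Victoria")$record_id, 1L)
  none <- make_records(2)
  none$stage_code <- c("C", "E")
  expect_equal(nrow(select_onset(none)), 0)
})

test_that("IQR fences use linear-interpolation quartiles", {
  r <- iqr_filter(c(100, 101, 102, 103, 130))
  expect_equal(r$removed, 130)
  expect_equal(unname(r$fences), c(98, 106))
  # constant input removes nothing
  r2 <- iqr_filter(rep(50, 6))
  expect_equal(length(r2$removed), 0)
  # fewer than 4 values pass through
  r3 <- iqr_filter(c(1, 100, 1000))
  expect_true(r3$passed_through)
  expect_equal(r3$kept, c(1, 100, 1000))
})

test_that("IQR filter matches brute force and never removes the median", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    v <- round(rnorm(n, 100, sample(c(1, 5, 20), 1)) +
                 sample(c(0, 40), n, replace = TRUE, prob = c(0.9, 0.1)))
    mine <- iqr_filter(v)
    ref <- oracle_iqr(v)
    expect_equal(sort(mine$kept), sort(ref$kept))
    expect_equal(sort(mine$removed), sort(ref$removed))
    # the median always lies inside the fences, so it is never filtered
    expect_gte(median(v), mine$fences[[1]])
    expect_lte(median(v), mine$fences[[2]])
  }
})

test_that("records aggregate onto grid cells by mean flowering day", {
  one <- make_records(1, date = as.Date("2022-04-10")) # DOY 100
  a1 <- aggregate_by_cell(one)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$onset_doy, 100)
  expect_equal(a1$n, 1L)
  # two records in one cell average fractionally
  two <- make_records(2, date = as.Date("2022-04-10") + c(0, 3))
  a2 <- aggregate_by_cell(two)
  expect_equal(nrow(a2), 1)
  expect_equal(a2$onset_doy, 101.5)
  # cell centers are reported
  expect_equal(a2$latitude, 51.55)
  expect_equal(a2$longitude, -0.95)
  # distinct cells stay distinct
  three <- make_records(3, lat = c(51.51, 53.22, 55.99))
  a3 <- aggregate_by_cell(three)
  expect_equal(nrow(a3), 3)
  expect_equal(sum(a3$n), 3L)
})

test_that("latitude-patterned split labels every fourth cell as validation", {
  obs <- data.frame(cell_id = sprintf("c%02d", 1:92),
                    latitude = seq(50, 58, length.out = 92),
                    longitude = -1)
  sp <- split_cal_val(obs)
  expect_equal(sum(sp$split == "validation"), 23)
  expect_equal(sum(sp$split == "calibration"), 69)
  expect_equal(sp$split[1], "validation") # southernmost first
  # 4 observations: one full cycle
  sp4 <- split_cal_val(obs[1:4, ])
  expect_equal(sum(sp4$split == "validation"), 1)
  expect_equal(sp4$split[1], "validation")
  # validation count is ceil(n / 4) for arbitrary n
  for (n in c(5, 11, 20, 33)) {
    spn <- split_cal_val(obs[1:n, ])
    expect_equal(sum(spn$split == "validation"), ceiling(n / 4))
    expect_true(all(diff(spn$latitude) >= 0))
  }
  expect_warning(sp3 <- split_cal_val(obs[1:3, ]), "fewer than 4")
  expect_true(all(sp3$split == "calibration"))
})

test_that("cleaning is idempotent", {
  truth <- small_study(12)$truth
  recs <- gen_records(truth, observation_config(records_per_cell = 4,
                                                noise_sd = 2,
                                                outlier_rate = 0.05,
                                                missing_photo_rate = 0.1,
                                                seed = 9))
  once <- clean_records(recs)
  twice <- clean_records(once$kept)
  expect_equal(twice$kept, once$kept)
  expect_equal(nrow(twice$log), 0)
})
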