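test_that("GDH response hits its closed-form anchor points and is continuous", {
  p <- phenoflex_params(Tu = 25, Tb = 4, Tc = 36)
  expect_equal(gdh_value(4, p), 0)
  expect_equal(gdh_value(36, p), 0)
  expect_equal(gdh_value(-5, p), 0)
  expect_equal(gdh_value(50, p), 0)
  expect_equal(gdh_value(25, p), 21)      # cos(2*pi) = 1 forces Tu - Tb
  expect_equal(gdh_value(14.5, p), 10.5)  # midpoint of the rising branch
  # continuity on a fine grid across both branch boundaries
  grid <- seq(2, 38, by = 0.001)
  g <- gdh_value(grid, p)
  expect_lt(max(abs(diff(g))), 0.05)
  # the response peaks exactly at Tu
  expect_equal(grid[which.max(g)], 25, tolerance = 1e-6)
})

test_that("precursor relaxes monotonically to its steady state below 1", {
  p <- phenoflex_params()
  temp <- 20 # xs < 1 here, so no conversion ever happens
  TK <- temp + 273.15
  xs <- (p[["A0"]] / p[["A1"]]) * exp(-(p[["E0"]] - p[["E1"]]) / TK)
  expect_lt(xs, 1)
  x <- 0
  xs_gap <- numeric(300)
  for (i in 1:300) {
    st <- chill_step(x, temp, p)
    expect_equal(st$delta, 0)
    xs_gap[i] <- xs - st$x
    x <- st$x
  }
  expect_true(all(diff(xs_gap) < 1e-12)) # gap shrinks monotonically
  expect_equal(x, xs, tolerance = 1e-6)
  # single step from x = 0 equals xs (1 - exp(-k1))
  k1 <- p[["A1"]] * exp(-p[["E1"]] / TK)
  expect_equal(chill_step(0, temp, p)$x, xs * (1 - exp(-k1)))
})

test_that("hot temperatures accumulate essentially no chill", {
  vic <- example_cultivar_params()$Victoria
  for (par in example_cultivar_params()) {
    cc <- chill_response_curve(par, temps = 25, hours = 1200)
    expect_lt(cc$chill_portions, 0.1)
  }
  # literal loop agrees at 40 degrees C
  o <- oracle_engine(rep(40, 1200), vic)
  expect_lt(o$y[1200], 0.1)
})

test_that("transition weight is capped, anchored at yc and monotone", {
  p <- phenoflex_params(s1 = 0.5, yc = 40)
  expect_equal(heat_weight(40, p), 1)
  expect_equal(heat_weight(100, p), 1)
  expect_equal(heat_weight(0, p), exp(-20))
  set.seed(42)
  for (i in 1:20) {
    pr <- random_params()
    ys <- sort(runif(10, 0, 2 * pr[["yc"]]))
    expect_true(all(diff(heat_weight(ys, pr)) >= 0))
  }
})

test_that("bloom is reported at the hour the heat threshold is crossed", {
  p <- example_cultivar_params()$Victoria
  p[["yc"]] <- 15 # modest chill requirement so the transition happens early
  h <- constant_hourly(8, n_days = 80) # good chilling temperature
  # warm it later so heat can accumulate
  h$temp[h$date >= as.Date("2021-12-15")] <- 12
  run <- predict_bloom(h, p, season_start = as.Date("2021-11-01"),
                       check_coverage = FALSE, keep_trajectory = TRUE)
  z <- run$trajectory$z
  target_hour <- 1500
  zc_new <- z[target_hour]
  expect_gt(zc_new, z[target_hour - 1]) # strictly increasing there
  p2 <- p
  p2[["zc"]] <- zc_new
  run2 <- predict_bloom(h, p2, season_start = as.Date("2021-11-01"),
                        check_coverage = FALSE, keep_trajectory = TRUE)
  expect_equal(run2$bloom_hour, target_hour)
  expect_gte(run2$trajectory$z[run2$bloom_hour], p2[["zc"]])
  expect_lt(run2$trajectory$z[run2$bloom_hour - 1], p2[["zc"]])
})

test_that("cold springs below the GDH base never bloom", {
  p <- example_cultivar_params()$Victoria
  h <- constant_hourly(8, n_days = 120)
  h$temp[h$date >= as.Date("2022-01-01")] <- 2 # below Tb = 6.66 forever
  run <- predict_bloom(h, p, season_start = as.Date("2021-11-01"),
                       check_coverage = FALSE)
  expect_false(run$bloomed)
  expect_true(is.na(run$bloom_doy))
})

test_that("chill and heat trajectories are non-decreasing and deterministic", {
  study <- small_study(4)
  h <- study$temps[[1]]
  run1 <- predict_bloom(h, study$par, keep_trajectory = TRUE)
  run2 <- predict_bloom(h, study$par, keep_trajectory = TRUE)
  expect_identical(run1, run2)
  expect_true(all(diff(run1$trajectory$y) >= 0))
  expect_true(all(diff(run1$trajectory$z) >= 0))
  expect_error(predict_bloom(h[1:2000, ], study$par), "cover")
})

test_that("engine agrees with the literal hour-loop oracle", {
  set.seed(99)
  for (i in 1:25) {
    pr <- random_params()
    temp <- runif(1, -5, 10) + cumsum(rnorm(500, 0, 0.8))
    res <- pf_run_cpp(temp, as.numeric(pr), keep_traj = TRUE)
    o <- oracle_engine(temp, pr)
    expect_lt(max(abs(res$y_traj - o$y)), 1e-9)
    expect_lt(max(abs(res$z_traj - o$z)), 1e-9)
    expect_equal(if (res$bloom_hour < 0) NA_integer_ else res$bloom_hour,
                 o$bloom)
  }
})

test_that("response curves peak at the expected temperatures", {
  for (nm in names(example_cultivar_params())) {
    par <- example_cultivar_params()[[nm]]
    hc <- heat_response_curve(par, temps = seq(0, 40, by = 0.01))
    expect_equal(hc$temp_C[which.max(hc$gdh)], par[["Tu"]], tolerance = 0.02,
                 label = paste("heat optimum", nm))
    cc <- chill_response_curve(par, temps = seq(0, 20, by = 0.5))
    opt <- cc$temp_C[which.max(cc$chill_portions)]
    expect_gt(opt, 5)
    expect_lt(opt, 10)
  }
})

test_that("uniform warming never delays bloom in a heat-limited season", {
  # construct a season where chill is safely satisfied in midwinter and bloom
  # waits on spring heat: a cool chilling plateau followed by a slow ramp
  p <- example_cultivar_params()$Victoria
  n_days <- 242
  dates <- seq(as.Date("2021-11-01"), by = "day", length.out = n_days)
  plateau <- as.numeric(dates < as.Date("2022-03-21"))
  ramp <- cumsum(1 - plateau) / sum(1 - plateau)
  day_temp <- 7.5 * plateau + (1 - plateau) * (7.5 + 8.5 * ramp)
  h <- data.frame(date = rep(dates, each = 24), hour = rep(0:23, n_days),
                  temp = rep(day_temp, each = 24))
  base <- predict_bloom(h, p, season_start = dates[1])
  expect_true(base$bloomed)
  for (delta in c(0.5, 1)) {
    h2 <- h
    h2$temp <- h$temp + delta
    warm <- predict_bloom(h2, p, season_start = dates[1])
    expect_true(warm$bloomed)
    expect_lte(warm$bloom_doy, base$bloom_doy)
  }
})

test_that("parameter sets are validated and round-trip through JSON", {
  expect_error(phenoflex_params(Tu = 5, Tb = 6), "Tb < Tu < Tc")
  expect_error(phenoflex_params(yc = -1), "positive")
  expect_error(as_phenoflex_params(c(yc = 1)), "missing parameters")
  p <- example_cultivar_params()$Stella
  f <- tempfile(fileext = ".json")
  write_params_json(p, f)
  expect_equal(read_params_json(f), p)
  unlink(f)
})
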