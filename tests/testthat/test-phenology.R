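test_that("scaling divides by the within-season maximum", {
  ser <- make_series(c(0, 10, 20, 30), c(0, 0.2, 0.8, 0.8))
  expect_equal(scale_series(ser)$p_scaled, c(0, 0.25, 1, 1))
  # already peaking at 1: identity
  ser2 <- make_series(c(0, 10, 20), c(0, 0.5, 1))
  expect_equal(scale_series(ser2)$p_scaled, ser2$p_raw)
  # 21% never fertilized: peak rescaled to exactly 1
  ser3 <- make_series(c(0, 10, 20), c(0.05, 0.40, 0.79))
  expect_equal(max(scale_series(ser3)$p_scaled), 1)
  expect_error(scale_series(make_series(c(0, 10), c(0, 0))), "no brooding")
})

test_that("scaling then fitting is invariant to multiplying p_raw by a constant", {
  withr::local_seed(7)
  days <- seq(0, 84, by = 7)
  p <- pmin(pmax(plogis((days - 40) / 6) + rnorm(length(days), 0, 0.03), 0), 1)
  base <- scale_series(make_series(days, p))
  m0 <- estimate_midpoint(fit_logistic(base$day_index, base$p_scaled, "rising"))
  for (k in c(0.3, 0.65, 1 / max(p))) {
    sk <- scale_series(make_series(days, p * k))
    mk <- estimate_midpoint(fit_logistic(sk$day_index, sk$p_scaled, "rising"))
    expect_equal(mk, m0, tolerance = 1e-8)
  }
})

test_that("the series splits at the midpoint of peak-brooding dates", {
  days <- c(16, 23, 30, 37, 44, 51, 58)
  p <- c(0.10, 0.50, 0.97, 0.99, 0.96, 0.80, 0.30)
  parts <- split_series(scale_series(make_series(days, p)))
  expect_equal(parts$split_day, 37)
  expect_true(37 %in% parts$fertilization$day_index)
  expect_true(37 %in% parts$release$day_index) # shared peak anchor
  expect_equal(max(parts$fertilization$day_index), 37)
  expect_equal(min(parts$release$day_index), 37)

  # single point above threshold
  p1 <- c(0.10, 0.30, 0.50, 0.99, 0.90, 0.60, 0.20)
  expect_equal(split_series(scale_series(make_series(days, p1)))$split_day, 37)

  # plateau with an even count: split falls between observations
  days2 <- seq(50, 100, by = 10)
  p2 <- c(0.3, 0.96, 0.97, 0.98, 0.99, 0.5)
  parts2 <- split_series(scale_series(make_series(days2, p2)))
  expect_equal(parts2$split_day, 75)
  expect_false(75 %in% days2)

  # nothing above threshold: informative error
  low <- scale_series(make_series(days, p * 0.9))
  low$p_scaled <- low$p_scaled * 0.9
  expect_error(split_series(low, threshold = 0.95), "max")
})

test_that("the threshold comparison is strict", {
  days <- c(10, 20, 30, 40, 50)
  ser <- scale_series(make_series(days, c(0.1, 0.95, 1.0, 0.95, 0.2)))
  # 0.95 does not exceed 0.95: only day 30 is peak
  expect_equal(split_series(ser, threshold = 0.95)$split_day, 30)
})

test_that("the F50 validity rule is strict at 60%", {
  expect_true(check_f50_valid(tibble::tibble(day_index = c(1, 10),
                                             p_scaled = c(0.10, 0.9))))
  expect_false(check_f50_valid(tibble::tibble(day_index = c(1, 10),
                                              p_scaled = c(0.60, 0.9))))
  # sampling that began mid-fertilization
  expect_false(check_f50_valid(tibble::tibble(day_index = c(1, 10),
                                              p_scaled = c(0.72, 1.0))))
})

test_that("trimming removes windows and protects minimum series length", {
  days <- c(10, 24, 38, 52, 66, 80, 87, 94, 108)
  ser <- make_series(days, c(0.05, 0.3, 0.8, 1, 1, 0.4, 0.45, 0.5, 1))
  out <- trim_anomalous(ser, list(c(78, 96)))
  expect_equal(nrow(out), nrow(ser) - 3)
  expect_false(any(out$day_index >= 78 & out$day_index <= 96))
  expect_identical(trim_anomalous(ser, list()), ser)
  expect_error(trim_anomalous(ser, list(c(0, 100))), "fewer than 3")
})

test_that("the dip diagnostic reports mid-season drops before late embryos", {
  days <- c(10, 24, 38, 52, 66, 80, 94, 108, 122)
  p <- c(0.05, 0.4, 0.9, 1.0, 0.5, 0.98, 1.0, 0.9, 0.3)
  late <- c(0, 0, 0, 0, 0, 0, 20, 60, 20)
  ser <- scale_series(make_series(days, p, n_late = late))
  dips <- detect_dips(ser)
  expect_equal(dips$day_index, 66)
  expect_gte(dips$dip_depth[1], 0.2)
  # same dip after late-stage embryos appeared: not a candidate
  late2 <- c(0, 0, 0, 20, 20, 20, 20, 60, 20)
  ser2 <- scale_series(make_series(days, p, n_late = late2))
  expect_equal(nrow(detect_dips(ser2)), 0)
})

test_that("estimate_phenology composes the pipeline and carries flags", {
  # noiseless two-limb season: rising then falling logistic
  days <- seq(7, 240, by = 7)
  p <- plogis((days - 55) / 3) * plogis(-(days - 170) / 8)
  ser <- make_series(days, round(p * 100) / 100)
  est <- estimate_phenology(ser)
  expect_s3_class(est, "phenology_estimates")
  expect_equal(est$f50, 55, tolerance = 1)
  expect_equal(est$lr50, 170, tolerance = 1.5)
  expect_equal(est$duration_days, est$lr50 - est$f50)
  expect_gt(est$lr50, est$f50)
  expect_true(est$f50_valid)
  expect_length(est$flags[[1]], 0)
})

test_that("recovered duration is close to truth on a generated season", {
  # temperature-independent development makes the true duration exact:
  # D = exp(a) = 115 d for every adult, true F50 at day 55
  cfg <- sim_config(a = log(115), b = -1e-9, sigma_f = 3, sigma_r = 1,
                    visit_fall_every = 7, visit_winter_every = 7)
  tt <- sim_temperature(cfg, "N1", 2021, seed = 401)
  pop <- sim_population(cfg, tt, true_f50 = 55, seed = 402)
  surv <- sim_survey(cfg, pop, sim_visit_schedule(cfg), 2021, "N1", seed = 403)
  est <- estimate_phenology(to_season_axis(surv))
  expect_equal(est$duration_days, 115, tolerance = 2)
})

test_that("a warm fast season broods for under 70 days", {
  cfg <- sim_config()
  tt <- sim_temperature(cfg, "S1", 2021, seed = 501)
  pop <- sim_population(cfg, tt, true_f50 = 62, seed = 502)
  surv <- sim_survey(cfg, pop, sim_visit_schedule(cfg), 2021, "S1", seed = 503)
  est <- estimate_phenology(to_season_axis(surv))
  expect_lt(est$duration_days, 70)
})

test_that("calendar arithmetic for durations crosses the New Year", {
  f50 <- season_day("11-01")
  lr50 <- season_day("02-01")
  expect_equal(lr50 - f50, 92)
})

test_that("trim windows configured per site-season set the trimmed flag", {
  days <- c(10, 24, 38, 52, 66, 80, 94, 108, 122, 136, 150, 164, 178)
  p <- plogis((days - 55) / 4) * plogis(-(days - 150) / 6)
  p[6] <- 0.45 # anomalous dip at day 80
  ser <- make_series(days, round(p * 100) / 100)
  win <- tibble::tibble(site = "A", season = "2021-2022",
                        start_day = 78, end_day = 82)
  est <- estimate_phenology(ser, exclude_windows = win)
  expect_true("trimmed" %in% est$flags[[1]])
  est_raw <- estimate_phenology(ser)
  # removing the dip moves F50 back toward the generating value
  expect_lt(abs(est$f50 - 55), abs(est_raw$f50 - 55) + 1e-9)
})
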