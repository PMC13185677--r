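#' Configuration for the synthetic-study generator
#'
#' Builds the full parameter set for [sim_study()]. The defaults describe a
#' study of four sites -- two warm "southern" and two cold "northern" shores
#' -- sampled over three seasons, with the statistical structure the
#' analysis assumes: seasonal + diel + tidal (12.42-h) temperature cycles
#' with AR(1) noise; per-adult fertilization days drawn from a logistic
#' distribution (so the population fertilized fraction is exactly a
#' logistic CDF); temperature-dependent embryonic development following
#' `D(T) = exp(a + b T)` with `b < 0`, integrated over the daily-mean
#' temperature each adult experiences; and periodic multinomial sampling of
#' up to 100 adults per visit, every 3 weeks in early fall and every 10
#' days thereafter.
#'
#' @param sites Tibble of per-site temperature and phenology parameters;
#'   see the default for the required columns.
#' @param start_years Season start years (Sep of each year opens a season).
#' @param a,b Duration-law coefficients: `D(T) = exp(a + b T)` days at
#'   constant temperature `T` deg C. Defaults span roughly 143 d at 2 deg C
#'   to 47 d at 10 deg C.
#' @param sigma_f Between-adult spread of fertilization dates (SD, days).
#' @param sigma_r Per-adult noise on the release day (SD, days).
#' @param frac_never_fert Fraction of adults never fertilized in a season.
#' @param f50_temp_slope Generating response of true F50 to the season's
#'   fall temperature anomaly (days per deg C; warming delays).
#' @param f50_jitter_sd Season-level jitter of true F50 around the
#'   temperature response (SD, days).
#' @param duration_season_sd_ln Season-level lognormal SD of the duration
#'   law (biological year effects on development rate).
#' @param interannual_sd SD of the regional seasonal temperature anomaly,
#'   shared by all sites within a season (deg C); interannual variation in
#'   this region is spatially coherent.
#' @param site_anomaly_sd SD of the site-level deviation from the regional
#'   anomaly (deg C).
#' @param n_adults Adults sampled per visit (with replacement).
#' @param n_pop Size of the simulated adult population.
#' @param visit_fall_every,visit_winter_every,fall_until Visit cadence
#'   (days) before and after `fall_until` (day index of the cadence
#'   switch).
#' @param phase_doy Day-of-year of the warm seasonal peak.
#' @param diel_amplitude,tidal_amplitude,ar1,innovation_sd Shared
#'   short-period temperature parameters (deg C; AR(1) on hourly residuals).
#' @param subzero_seasons Optional tibble with columns `site`, `start_year`
#'   naming site-seasons into which an early-fall cold snap is injected
#'   (a smooth pulse of depth `snap_depth` deg C centered on day
#'   `snap_center`), used to exercise the subzero exclusion rule.
#' @param snap_center,snap_depth,snap_width Cold-snap pulse parameters
#'   (day index, deg C, days).
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(
    sites = tibble::tibble(
      site = c("S1", "S2", "N1", "N2"),
      annual_mean = c(11.0, 10.4, 8.0, 7.4),
      annual_amplitude = c(8.5, 8.5, 8.5, 8.5),
      base_f50 = c(62, 64, 56, 58)
    ),
    start_years = 2020:2022,
    a = 5.24, b = -0.14,
    sigma_f = 4, sigma_r = 3,
    frac_never_fert = 0.02,
    f50_temp_slope = 3.7,
    f50_jitter_sd = 1.5,
    duration_season_sd_ln = 0.08,
    interannual_sd = 0.8, site_anomaly_sd = 0.3,
    n_adults = 100, n_pop = 300,
    visit_fall_every = 21, visit_winter_every = 10, fall_until = 75,
    phase_doy = 222,
    diel_amplitude = 2.0, tidal_amplitude = 1.5,
    ar1 = 0.7, innovation_sd = 0.5,
    subzero_seasons = NULL,
    snap_center = 40, snap_depth = 14, snap_width = 2) {
  cfg <- as.list(environment())
  stopifnot(b < 0, sigma_f >= 0, sigma_r >= 0, abs(ar1) < 1,
            n_adults >= 1, frac_never_fert >= 0, frac_never_fert < 1)
  structure(cfg, class = "sim_config")
}

# deterministic sub-seed below 2^31, so independent streams per site-season
sub_seed <- function(seed, site_i, season_i, stream) {
  (as.numeric(seed) * 7919 + site_i * 104729 +
     season_i * 1299721 + stream * 15485863) %% 2147483629
}

#' Simulate an hourly intertidal temperature series for one site-season
#'
#' Hourly series from Sep 1 to May 31: seasonal sinusoid + diel sinusoid +
#' 12.42-h tidal sinusoid + AR(1) noise, plus an optional seasonal anomaly
#' shift and early-fall cold-snap pulse. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param site Site id present in `config$sites`.
#' @param start_year Season start year.
#' @param seed Integer seed.
#' @param season_anomaly Additive deg C shift for this season.
#' @param cold_snap Inject the configured early-fall subzero pulse?
#' @return Tibble with `timestamp`, `temp_c` (hourly, gap-free).
#' @export
sim_temperature <- function(config, site, start_year, seed,
                            season_anomaly = 0, cold_snap = FALSE) {
  sp <- config$sites[config$sites$site == site, ]
  if (nrow(sp) != 1) abort(sprintf("unknown site '%s'", site))
  t0 <- as.POSIXct(sprintf("%d-09-01 00:00:00", start_year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-05-31 23:00:00", start_year + 1), tz = "UTC")
  ts <- seq(t0, t1, by = 3600)
  h <- as.numeric(ts - t0, units = "hours")
  doy <- as.POSIXlt(ts)$yday + h %% 24 / 24
  seasonal <- sp$annual_amplitude * cos(2 * pi * (doy - config$phase_doy) / 365.25)
  diel <- config$diel_amplitude * cos(2 * pi * (h %% 24 - 14) / 24)
  tidal <- config$tidal_amplitude * cos(2 * pi * h / 12.42)
  set.seed(seed)
  noise <- as.numeric(stats::filter(rnorm(length(h), 0, config$innovation_sd),
                                    config$ar1, method = "recursive"))
  temp <- sp$annual_mean + season_anomaly + seasonal + diel + tidal + noise
  if (cold_snap) {
    day <- h / 24
    temp <- temp - config$snap_depth *
      exp(-((day - config$snap_center) / config$snap_width)^2)
  }
  tibble::tibble(timestamp = ts, temp_c = temp)
}

# daily-mean temperatures and the cumulative development integral:
# rate on day d is 1/D(T_d); release when the integral since
# fertilization reaches 1. Returns a list with the per-day rates and the
# piecewise-linear cumulative integral evaluator.
development_clock <- function(temps, a, b) {
  day <- floor(as.numeric(temps$timestamp - temps$timestamp[1],
                          units = "days"))
  t_daily <- tapply(temps$temp_c, day, mean)
  rate <- exp(-(a + b * as.numeric(t_daily)))
  cum <- c(0, cumsum(rate))
  list(
    rate = rate, cum = cum, n_days = length(rate),
    at = function(t) {
      # cumulative development at (real) day t since series start
      t <- pmin(pmax(t, 0), length(rate))
      d <- pmin(floor(t), length(rate) - 1)
      cum[d + 1] + (t - d) * rate[d + 1]
    }
  )
}

# invert the cumulative integral: first t with clock$at(t) >= target
development_invert <- function(clock, target) {
  out <- rep(NA_real_, length(target))
  ok <- target <= clock$cum[length(clock$cum)]
  idx <- findInterval(target[ok], clock$cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1), clock$n_days)
  out[ok] <- (idx - 1) + (target[ok] - clock$cum[idx]) / clock$rate[idx]
  out
}

#' Simulate the reproductive history of one adult population
#'
#' Each adult's fertilization day is drawn from a logistic distribution
#' centered on the true F50 (scale `sigma_f * sqrt(3) / pi`, so the SD is
#' `sigma_f`); a configured fraction is never fertilized. Release occurs
#' when the cumulative development integral `int dt / D(T_daily(t))`
#' reaches 1, plus per-adult noise `sigma_r`. Adults whose development does
#' not complete by the end of the series are flagged `overwinter_failure`
#' and never appear as released.
#'
#' @param config A [sim_config()].
#' @param temps Hourly temperature tibble covering the season.
#' @param true_f50 True fertilization midpoint (day index).
#' @param seed Integer seed.
#' @param a_eff Effective duration-law intercept for this season (defaults
#'   to `config$a`; season-level effects enter here).
#' @return A list: `adults` tibble (`fert_day`, `release_day`,
#'   `never_fertilized`, `overwinter_failure`, `tissue_score1`), the
#'   development `clock`, and `true_lr50` / `true_duration` (the realized
#'   population median release day, and its offset from `true_f50`).
#' @export
sim_population <- function(config, temps, true_f50, seed, a_eff = config$a) {
  clock <- development_clock(temps, a_eff, config$b)
  set.seed(seed)
  n <- config$n_pop
  fert <- rlogis(n, location = true_f50, scale = config$sigma_f * sqrt(3) / pi)
  fert <- pmax(fert, 0.01) # cannot precede the series start
  never <- runif(n) < config$frac_never_fert
  release_det <- development_invert(clock, clock$at(fert) + 1)
  release <- release_det + rnorm(n, 0, config$sigma_r)
  release <- pmax(release, fert + 1)
  fail <- is.na(release_det)
  release[fail] <- NA_real_
  tissue1 <- runif(n) < 0.3
  true_lr50 <- median(release[!never], na.rm = TRUE)
  list(
    adults = tibble::tibble(
      fert_day = fert, release_day = release,
      never_fertilized = never, overwinter_failure = fail,
      tissue_score1 = tissue1
    ),
    clock = clock,
    true_lr50 = true_lr50,
    true_duration = true_lr50 - true_f50
  )
}

#' Default visit schedule for one season
#'
#' Visits every `visit_fall_every` days from day 10 through `fall_until`,
#' then every `visit_winter_every` days to the end of the series,
#' emulating sampling every 2--4 weeks in early fall and every 1--2 weeks
#' through winter and spring.
#'
#' @param config A [sim_config()].
#' @param last_day Final day index available (default 272, end of May).
#' @return Integer vector of visit day indices.
#' @export
sim_visit_schedule <- function(config, last_day = 272) {
  fall <- seq(10, config$fall_until, by = config$visit_fall_every)
  winter <- seq(max(fall) + config$visit_winter_every, last_day,
                by = config$visit_winter_every)
  c(fall, winter)
}

#' Simulate periodic surveys of a population
#'
#' At each visit, `n_adults` adults are drawn with replacement and
#' classified into embryo score classes by their development fraction `f`
#' at that date: unfertilized adults score 0 or 1 (a fixed per-adult
#' tissue attribute); brooding adults score 2 (`f < 0.25`), 3
#' (`f < 0.5`), 4 (`f < 0.8`), 4b (`f < 0.95`) or 5; released adults
#' score 0, mimicking pock-marked post-release tissue.
#'
#' @param config A [sim_config()].
#' @param population Result of [sim_population()].
#' @param visit_days Day indices of the visits.
#' @param start_year Season start year (visits dated from Sep 1).
#' @param site Site id recorded in the output.
#' @param seed Integer seed.
#' @return Survey tibble in the [read_survey_table()] layout.
#' @export
sim_survey <- function(config, population, visit_days, start_year, site, seed) {
  set.seed(seed)
  ad <- population$adults
  clock <- population$clock
  origin <- as.Date(sprintf("%d-09-01", start_year))
  rows <- purrr::map(visit_days, function(d) {
    pick <- sample.int(nrow(ad), config$n_adults, replace = TRUE)
    s <- ad[pick, ]
    score <- character(config$n_adults)
    unfert <- s$never_fertilized | s$fert_day > d
    released <- !unfert & !is.na(s$release_day) & s$release_day <= d
    brood <- !unfert & !released
    score[unfert] <- ifelse(s$tissue_score1[unfert], "1", "0")
    score[released] <- "0"
    if (any(brood)) {
      f <- pmin(clock$at(d) - clock$at(s$fert_day[brood]), 1)
      score[brood] <- as.character(cut(f, c(-Inf, 0.25, 0.5, 0.8, 0.95, Inf),
                                       labels = c("2", "3", "4", "4b", "5")))
    }
    counts <- table(factor(score, levels = embryo_scores()$score))
    out <- tibble::tibble(site = site, date = origin + d)
    out[score_cols()] <- as.list(as.numeric(counts))
    out
  })
  finalize_survey_tbl(dplyr::bind_rows(rows))
}

#' Simulate a complete multi-site, multi-season study
#'
#' Generates, for every site and season in the configuration: a seasonal
#' temperature anomaly, the hourly temperature series, a true F50 that
#' responds to the fall anomaly at `f50_temp_slope` days per deg C, the
#' adult population with temperature-driven development, and the periodic
#' survey counts. Ground truth (true F50, LR50, duration, and the
#' generating law) is returned alongside, for parameter-recovery tests.
#' Byte-identical outputs for identical `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; all site-season streams derive from it.
#' @param dir Optional directory: when given, survey/temperature/truth CSVs
#'   and the echoed config are written there.
#' @return A list of class `sim_study`: `surveys` (one tibble, all sites),
#'   `temperatures` (tibble with `site`, `start_year`, `timestamp`,
#'   `temp_c`), `truth` (per site-season ground truth) and `config`.
#' @export
sim_study <- function(config = sim_config(), seed = 1, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  surveys <- list(); temps_all <- list(); truth <- list()
  regional <- vapply(seq_along(config$start_years), function(j) {
    set.seed(sub_seed(seed, 0, j, 4))
    rnorm(1, 0, config$interannual_sd)
  }, numeric(1))
  for (i in seq_len(nrow(config$sites))) {
    site <- config$sites$site[i]
    for (j in seq_along(config$start_years)) {
      yr <- config$start_years[j]
      set.seed(sub_seed(seed, i, j, 0))
      anom <- regional[j] + rnorm(1, 0, config$site_anomaly_sd)
      f50_true <- config$sites$base_f50[i] + config$f50_temp_slope * anom +
        rnorm(1, 0, config$f50_jitter_sd)
      a_eff <- config$a + rnorm(1, 0, config$duration_season_sd_ln)
      snap <- !is.null(config$subzero_seasons) &&
        any(config$subzero_seasons$site == site &
              config$subzero_seasons$start_year == yr)
      temps <- sim_temperature(config, site, yr, seed = sub_seed(seed, i, j, 1),
                               season_anomaly = anom, cold_snap = snap)
      pop <- sim_population(config, temps, f50_true,
                            seed = sub_seed(seed, i, j, 2), a_eff = a_eff)
      surv <- sim_survey(config, pop, sim_visit_schedule(config), yr, site,
                         seed = sub_seed(seed, i, j, 3))
      surveys[[length(surveys) + 1]] <- surv
      temps_all[[length(temps_all) + 1]] <-
        dplyr::mutate(temps, site = site, start_year = yr, .before = 1)
      truth[[length(truth) + 1]] <- tibble::tibble(
        site = site, start_year = yr,
        season = paste0(yr, "-", yr + 1),
        season_anomaly = anom,
        true_f50 = f50_true, true_lr50 = pop$true_lr50,
        true_duration = pop$true_duration,
        a = config$a, b = config$b, a_eff = a_eff,
        cold_snap = snap
      )
    }
  }
  out <- structure(list(
    surveys = dplyr::bind_rows(surveys),
    temperatures = dplyr::bind_rows(temps_all),
    truth = dplyr::bind_rows(truth),
    config = config
  ), class = "sim_study")
  if (!is.null(dir)) write_sim_study(out, dir)
  out
}

#' Write a simulated study to disk
#'
#' One survey CSV for all sites, one temperature CSV per site-season, the
#' ground-truth CSV, and the configuration echoed as JSON (the single
#' source of truth for the run).
#'
#' @param study A `sim_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_survey_table(study$surveys, file.path(dir, "surveys.csv"))
  tkeys <- dplyr::distinct(study$temperatures, .data$site, .data$start_year)
  for (k in seq_len(nrow(tkeys))) {
    sel <- study$temperatures$site == tkeys$site[k] &
      study$temperatures$start_year == tkeys$start_year[k]
    write_temperature_csv(
      study$temperatures[sel, c("timestamp", "temp_c")],
      file.path(dir, sprintf("temps_%s_%d.csv", tkeys$site[k], tkeys$start_year[k]))
    )
  }
  readr::write_csv(study$truth, file.path(dir, "ground_truth.csv"))
  cfg <- study$config
  cfg$sites <- as.data.frame(cfg$sites)
  if (!is.null(cfg$subzero_seasons)) cfg$subzero_seasons <- as.data.frame(cfg$subzero_seasons)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a simulated study back from disk
#'
#' @param dir Directory written by [write_sim_study()].
#' @return A list with `surveys`, `temperatures` and `truth` tibbles.
#' @export
read_sim_study <- function(dir) {
  files <- list.files(dir, pattern = "^temps_.*\\.csv$", full.names = TRUE)
  temps <- purrr::map(files, function(f) {
    key <- sub("^temps_(.*)_(\\d{4})\\.csv$", "\\1|\\2", basename(f))
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    dplyr::mutate(read_temperature_csv(f), site = parts[1],
                  start_year = as.integer(parts[2]), .before = 1)
  })
  list(
    surveys = read_survey_table(file.path(dir, "surveys.csv")),
    temperatures = dplyr::bind_rows(temps),
    truth = readr::read_csv(file.path(dir, "ground_truth.csv"),
                            show_col_types = FALSE)
  )
}
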