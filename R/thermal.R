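#' Regularize a temperature series to an exact hourly grid
#'
#' Modeled intertidal series arrive at 30-min resolution and logger series
#' at various cadences; all analyses run on an hourly grid. Points falling
#' exactly on the hour are kept (subsampling, not averaging); interior gaps
#' are filled by linear interpolation, with a warning for gaps longer than
#' 24 h. Leading and trailing partial hours are dropped rather than
#' extrapolated.
#'
#' @param temps Tibble with `timestamp` (POSIXct) and `temp_c`.
#' @return Tibble on an exact 3600-s grid with no missing values.
#' @export
regularize_hourly <- function(temps) {
  if (nrow(temps) < 2) abort("at least 2 temperature points are required")
  t_num <- as.numeric(temps$timestamp)
  if (any(diff(t_num) <= 0)) abort("timestamps must be strictly increasing")
  t0 <- ceiling(t_num[1] / 3600) * 3600
  t1 <- floor(t_num[length(t_num)] / 3600) * 3600
  if (t1 <= t0) abort("series too short to cover an hourly grid")
  grid <- seq(t0, t1, by = 3600)
  on_hour <- t_num %% 3600 == 0
  idx <- match(grid, t_num[on_hour])
  vals <- temps$temp_c[on_hour][idx]
  if (anyNA(vals)) {
    known <- which(!is.na(vals))
    if (length(known) < 2) abort("too few on-hour points to interpolate")
    gaps <- diff(known)
    if (any(gaps > 24)) {
      warn(sprintf("interpolating across %d gap(s) longer than 24 h (longest: %d h)",
                   sum(gaps > 24), max(gaps)))
    }
    vals <- approx(grid[known], vals[known], xout = grid, rule = 1)$y
    keep <- !is.na(vals) # leading/trailing gaps stay absent
    grid <- grid[keep]; vals <- vals[keep]
  }
  tibble::tibble(
    timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    temp_c = vals
  )
}

#' PL64 low-pass filter weights
#'
#' The PL64 filter is the symmetric FIR filter used in physical
#' oceanography to remove tidal and diurnal variability from hourly series:
#' a cosine-Lanczos squared taper with a 64-h half width (129 hourly taps)
#' and half-amplitude response at a 33-h period. The half-kernel weights are
#' `(2 sin(2 f t) - sin(f t) - sin(3 f t)) / (f^2 t^3)` with `t = pi j`,
#' `f = 1/cutoff`, center weight `2 f`, normalized to unit sum (exact unit
#' DC gain).
#'
#' @param half_width Half width in hourly taps (default 64).
#' @param cutoff Half-amplitude period in hours (default 33).
#' @return Numeric kernel of length `2 * half_width + 1` summing to 1.
#' @export
pl64_weights <- function(half_width = 64, cutoff = 33) {
  fq <- 1 / cutoff
  j <- seq_len(half_width)
  t <- pi * j
  w <- (2 * sin(2 * fq * t) - sin(fq * t) - sin(3 * fq * t)) / (fq^2 * t^3)
  k <- c(rev(w), 2 * fq, w)
  k / sum(k)
}

#' Frequency response of the PL64 kernel
#'
#' Amplitude response `H(T) = sum_j w_j cos(2 pi j / T)` of the symmetric
#' kernel at a sinusoid of period `period_hours`. Being symmetric, the
#' filter has exactly zero phase shift at all frequencies.
#'
#' @param period_hours Sinusoid period(s) in hours.
#' @inheritParams pl64_weights
#' @return Amplitude gain(s), 1 = fully passed, 0 = fully removed.
#' @export
pl64_response <- function(period_hours, half_width = 64, cutoff = 33) {
  k <- pl64_weights(half_width, cutoff)
  j <- seq(-half_width, half_width)
  vapply(period_hours, function(p) sum(k * cos(2 * pi * j / p)), numeric(1))
}

#' Low-pass filter an hourly temperature series with PL64
#'
#' Convolves the hourly series with the PL64 kernel. The first and last
#' `half_width` hours cannot be computed without padding and are returned
#' as `NA` (dropping, not padding, avoids biasing window means near series
#' boundaries).
#'
#' @param temps Hourly, gap-free tibble from [regularize_hourly()].
#' @inheritParams pl64_weights
#' @return The input tibble with `temp_c` replaced by its filtered values
#'   (`NA` in the two edge regions).
#' @export
pl64_filter <- function(temps, half_width = 64, cutoff = 33) {
  check_hourly(temps)
  k <- pl64_weights(half_width, cutoff)
  if (nrow(temps) < length(k)) {
    abort(sprintf("series of %d h is shorter than the %d-tap filter kernel",
                  nrow(temps), length(k)))
  }
  temps$temp_c <- as.numeric(stats::filter(temps$temp_c, k, sides = 2))
  temps
}

check_hourly <- function(temps) {
  if (anyNA(temps$temp_c)) abort("series must be gap-free; run regularize_hourly() first")
  d <- diff(as.numeric(temps$timestamp))
  if (length(d) > 0 && any(d != 3600)) {
    abort("series must be on an exact hourly grid; run regularize_hourly() first")
  }
  invisible(temps)
}

#' Seasonal averaging windows
#'
#' The two fixed fall windows used for the temperature analysis, as closed
#' calendar-day intervals within a season starting Sep 1: "early fall" is
#' Sep 22 to Nov 20 (the period when fertilization typically occurs, used
#' for subzero screening) and "fall" is Sep 22 to Dec 22 (92 days, used for
#' the fall temperature anomaly).
#'
#' @param start_year Season start year (the September year).
#' @return A list with POSIXct 2-vectors `early_fall` and `fall`, spanning
#'   from 00:00 on the first day to 23:00 on the last day.
#' @export
season_windows <- function(start_year) {
  win <- function(from, to) {
    as.POSIXct(paste0(c(paste0(start_year, "-", from, " 00:00:00"),
                        paste0(start_year, "-", to, " 23:00:00"))), tz = "UTC")
  }
  list(early_fall = win("09-22", "11-20"), fall = win("09-22", "12-22"))
}

#' Mean temperature over a time window
#'
#' Arithmetic mean of the hourly (typically filtered) values with
#' timestamps inside the closed interval `[start, end]`. The window must be
#' covered by valid (non-`NA`) values over at least `min_coverage` of its
#' expected hourly length; otherwise an error reports the coverage, so that
#' filter-edge gaps never silently bias a mean.
#'
#' @param temps Hourly temperature tibble (`NA` allowed at filter edges).
#' @param start,end Window bounds (POSIXct, or Date taken at midnight UTC).
#' @param min_coverage Minimum fraction of expected hours present
#'   (default 0.9).
#' @return Mean temperature in deg C.
#' @export
window_mean <- function(temps, start, end, min_coverage = 0.9) {
  start <- to_utc(start); end <- to_utc(end)
  if (end <= start) abort("window end must be after start")
  sel <- temps$timestamp >= start & temps$timestamp <= end
  vals <- temps$temp_c[sel]
  vals <- vals[!is.na(vals)]
  expected <- floor(as.numeric(end - start, units = "hours")) + 1
  coverage <- length(vals) / expected
  if (length(vals) == 0) abort("window does not overlap the series")
  if (coverage < min_coverage) {
    abort(sprintf("window covered at %.0f%% (< %.0f%%) by valid hourly values",
                  100 * coverage, 100 * min_coverage))
  }
  mean(vals)
}

to_utc <- function(x) {
  if (inherits(x, "Date")) as.POSIXct(format(x), tz = "UTC") else x
}

#' Detect subzero filtered temperatures in a window
#'
#' Fertilization can be disrupted by freezing conditions; seasons whose
#' filtered series dips below 0 deg C during early fall are flagged and
#' later excluded from the F50-anomaly regression.
#'
#' @param temps Filtered hourly temperature tibble.
#' @param window POSIXct 2-vector, typically
#'   `season_windows(year)$early_fall`.
#' @return `TRUE` if any valid value in the window is below 0 deg C.
#' @export
detect_subzero <- function(temps, window) {
  sel <- temps$timestamp >= window[1] & temps$timestamp <= window[2]
  vals <- temps$temp_c[sel]
  any(vals < 0, na.rm = TRUE)
}

#' Site-centered fall temperature and F50 anomalies
#'
#' For each site, averages the fall temperature and the F50 day over the
#' seasons with a usable F50, then subtracts these site means from the
#' per-season values. Anomalies therefore sum to zero within each site,
#' and cross-site temperature differences are removed before regression.
#'
#' @param records Tibble with one row per site-season and columns `site`,
#'   `season`, `fall_temp_mean`, `f50`; optional `f50_valid` (default all
#'   `TRUE`) and `subzero_early_fall` (default all `FALSE`, carried
#'   through).
#' @return Tibble of the valid-F50 rows with `fall_temp_anomaly` and
#'   `f50_anomaly` columns added. Errors if any site contributes fewer than
#'   2 valid seasons (a single season has no anomaly).
#' @export
compute_anomalies <- function(records) {
  if (!"f50_valid" %in% names(records)) records$f50_valid <- TRUE
  if (!"subzero_early_fall" %in% names(records)) records$subzero_early_fall <- FALSE
  valid <- dplyr::filter(records, .data$f50_valid & !is.na(.data$f50))
  counts <- dplyr::count(valid, .data$site)
  if (any(counts$n < 2)) {
    abort(sprintf("anomalies undefined: site(s) %s have fewer than 2 seasons with valid F50",
                  paste(counts$site[counts$n < 2], collapse = ", ")))
  }
  valid |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(
      fall_temp_anomaly = .data$fall_temp_mean - mean(.data$fall_temp_mean),
      f50_anomaly = .data$f50 - mean(.data$f50)
    ) |>
    dplyr::ungroup()
}

#' Model-vs-logger error statistics
#'
#' Mean error and root-mean-square error of modeled minus logger
#' temperatures over the timestamp intersection of the two (hourly,
#' filtered) series.
#'
#' @param model,logger Hourly temperature tibbles.
#' @return One-row tibble with `me`, `rmse` and `n_hours`.
#' @export
model_error <- function(model, logger) {
  joined <- dplyr::inner_join(model, logger, by = "timestamp",
                              suffix = c("_model", "_logger"))
  joined <- joined[complete.cases(joined), ]
  if (nrow(joined) == 0) abort("the two series share no valid timestamps")
  d <- joined$temp_c_model - joined$temp_c_logger
  tibble::tibble(me = mean(d), rmse = sqrt(mean(d^2)), n_hours = nrow(joined))
}
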