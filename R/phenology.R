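#' Scale brooding proportions so each site-season peaks at 1
#'
#' Restricts inference to the individuals that reproduced: in some
#' site-seasons 10%--21% of adults never carry embryos even during peak
#' brooding, so raw fertilized proportions are divided by their within-season
#' maximum to make the logistic curves comparable across sites and years.
#'
#' @param series Brooding-series tibble from [to_season_axis()]; may contain
#'   several site-seasons.
#' @return The input with a `p_scaled` column (`p_raw / max(p_raw)` within
#'   each site-season; the maximum is exactly 1).
#' @export
scale_series <- function(series) {
  out <- series |>
    dplyr::group_by(.data$site, .data$season) |>
    dplyr::mutate(p_scaled = {
      if (max(.data$p_raw) <= 0) {
        abort(sprintf("no brooding observed at %s %s: all proportions are zero",
                      .data$site[1], .data$season[1]))
      }
      .data$p_raw / max(.data$p_raw)
    }) |>
    dplyr::ungroup()
  out
}

#' Split a scaled series into fertilization and larval-release limbs
#'
#' The transition point is the midpoint of the dates when the scaled
#' brooding proportion exceeds the threshold (strictly; default 95%), i.e.
#' the approximate middle of peak brooding. Observations on or before the
#' split day form the fertilization (rising) limb; observations on or after
#' it form the release (falling) limb, so an observation landing exactly on
#' the split day anchors both limbs.
#'
#' @param series Scaled brooding-series tibble for a single site-season.
#' @param threshold Scaled-proportion threshold defining peak brooding
#'   (default 0.95, exceeded strictly).
#' @return A list with elements `fertilization`, `release` (tibbles) and
#'   `split_day` (numeric).
#' @export
split_series <- function(series, threshold = 0.95) {
  stopifnot("p_scaled" %in% names(series))
  if (dplyr::n_distinct(series$site) > 1 || dplyr::n_distinct(series$season) > 1) {
    abort("split_series expects a single site-season")
  }
  peak <- series$day_index[series$p_scaled > threshold]
  if (length(peak) == 0) {
    abort(sprintf("no scaled proportion exceeds %.2f (max observed: %.3f)",
                  threshold, max(series$p_scaled)))
  }
  split_day <- (min(peak) + max(peak)) / 2
  list(
    fertilization = dplyr::filter(series, .data$day_index <= split_day),
    release = dplyr::filter(series, .data$day_index >= split_day),
    split_day = split_day
  )
}

#' Is an F50 estimate usable for the anomaly analysis?
#'
#' When field sampling begins after population-wide fertilization is already
#' underway, the rising limb is truncated and F50 is unreliable. An F50
#' estimate is retained only if the earliest scaled value on the
#' fertilization limb is below `max_start` (strictly; default 60%).
#'
#' @param fertilization Fertilization-limb tibble from [split_series()].
#' @param max_start Largest admissible first scaled value (default 0.60).
#' @return Logical scalar.
#' @export
check_f50_valid <- function(fertilization, max_start = 0.60) {
  if (nrow(fertilization) == 0) abort("empty fertilization limb")
  first <- fertilization$p_scaled[which.min(fertilization$day_index)]
  first < max_start
}

#' Remove observations inside configured exclusion windows
#'
#' A few series show anomalously low fertilization in mid-season, before any
#' late-stage embryos are observed (so before release could have occurred);
#' the logistic fits for those series are computed on a configured subset.
#' Windows are never inferred automatically -- see [detect_dips()] for the
#' diagnostic that reports candidates.
#'
#' @param series Brooding-series tibble for a single site-season.
#' @param exclude_windows List of 2-element numeric vectors
#'   `c(start_day, end_day)` (inclusive day-index intervals).
#' @return The series with in-window rows removed; at least 3 observations
#'   must remain.
#' @export
trim_anomalous <- function(series, exclude_windows = list()) {
  if (length(exclude_windows) == 0) return(series)
  drop <- rep(FALSE, nrow(series))
  for (w in exclude_windows) {
    stopifnot(length(w) == 2, w[1] <= w[2])
    drop <- drop | (series$day_index >= w[1] & series$day_index <= w[2])
  }
  out <- series[!drop, ]
  if (nrow(out) < 3) {
    abort("trimming leaves fewer than 3 observations")
  }
  out
}

#' Report candidate anomalous dips in a scaled series (diagnostic)
#'
#' Flags observations where the scaled proportion drops by at least
#' `min_drop` below the running maximum, later recovers to at least
#' `recover_to`, and occurs before the first observation of late-stage
#' embryos (so larval release cannot explain the drop). Diagnostic only:
#' trimming is always explicit via `exclude_windows`.
#'
#' @param series Scaled brooding-series tibble (any number of site-seasons).
#' @param min_drop Minimum drop below the running maximum (default 0.2).
#' @param recover_to Minimum later recovery level (default 0.95).
#' @return Tibble of candidate rows with the drop depth.
#' @export
detect_dips <- function(series, min_drop = 0.2, recover_to = 0.95) {
  stopifnot("p_scaled" %in% names(series))
  series |>
    dplyr::group_by(.data$site, .data$season) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$day_index)
      run_max <- cummax(g$p_scaled)
      later_max <- rev(cummax(rev(g$p_scaled)))
      first_late <- if (any(g$n_late > 0)) min(g$day_index[g$n_late > 0]) else Inf
      depth <- run_max - g$p_scaled
      cand <- depth >= min_drop & later_max >= recover_to & g$day_index < first_late
      g$dip_depth <- depth
      g[cand, c("day_index", "date", "p_scaled", "dip_depth")]
    }) |>
    dplyr::ungroup()
}

#' Estimate F50, LR50 and brooding duration for each site-season
#'
#' The full phenology procedure: scale proportions to peak at 1, apply any
#' configured trims, split at the midpoint of peak brooding, fit a
#' quasi-binomial logistic to each limb, invert each fit at 50%, and take
#' the brooding duration as `LR50 - F50` days. The F50 validity rule
#' (earliest scaled value < 60%) is evaluated per season and carried as a
#' flag; invalid F50s are still reported but are excluded from the anomaly
#' regression downstream.
#'
#' @param series Brooding-series tibble from [to_season_axis()]; any number
#'   of site-seasons.
#' @param threshold Peak-brooding split threshold (default 0.95).
#' @param f50_valid_max F50 validity cutoff on the earliest scaled value
#'   (default 0.60).
#' @param weights `"none"` (default: each visit contributes one proportion,
#'   mirroring the explicit normalization to proportions) or `"n"`
#'   (per-visit sample sizes as quasi-binomial weights).
#' @param exclude_windows Optional tibble with columns `site`, `season`,
#'   `start_day`, `end_day` giving per-site-season trim windows
#'   (inclusive day indices).
#' @return A tibble with one row per site-season: `site`, `season`,
#'   `start_year`, `f50`, `lr50`, `duration_days`, `f50_valid`, `split_day`,
#'   `flags` (list of character), plus list-columns `fit_fert`, `fit_rel`
#'   (the two `logistic_fit` objects) and `data` (the scaled series).
#' @export
estimate_phenology <- function(series, threshold = 0.95, f50_valid_max = 0.60,
                               weights = c("none", "n"),
                               exclude_windows = NULL) {
  weights <- arg_match(weights)
  scaled <- scale_series(series)
  groups <- scaled |>
    dplyr::group_by(.data$site, .data$season, .data$start_year) |>
    dplyr::group_split()
  rows <- purrr::map(groups, function(g) {
    flags <- character()
    win <- list()
    if (!is.null(exclude_windows)) {
      sel <- exclude_windows$site == g$site[1] & exclude_windows$season == g$season[1]
      if (any(sel)) {
        win <- purrr::map2(exclude_windows$start_day[sel],
                           exclude_windows$end_day[sel], c)
      }
    }
    g_trim <- trim_anomalous(g, win)
    if (length(win) > 0) flags <- c(flags, "trimmed")
    # trimming changes the observed maximum: rescale on the trimmed set
    g_trim$p_scaled <- g_trim$p_raw / max(g_trim$p_raw)
    parts <- split_series(g_trim, threshold = threshold)
    w_f <- if (weights == "n") parts$fertilization$n else NULL
    w_r <- if (weights == "n") parts$release$n else NULL
    fit_f <- fit_logistic(parts$fertilization$day_index,
                          parts$fertilization$p_scaled,
                          direction = "rising", weights = w_f)
    fit_r <- fit_logistic(parts$release$day_index,
                          parts$release$p_scaled,
                          direction = "falling", weights = w_r)
    if (fit_f$separation || fit_r$separation) flags <- c(flags, "separation")
    f50 <- estimate_midpoint(fit_f)
    lr50 <- estimate_midpoint(fit_r)
    tibble::tibble(
      site = g$site[1], season = g$season[1], start_year = g$start_year[1],
      f50 = f50, lr50 = lr50, duration_days = lr50 - f50,
      f50_valid = check_f50_valid(parts$fertilization, f50_valid_max),
      split_day = parts$split_day,
      flags = list(flags),
      fit_fert = list(fit_f), fit_rel = list(fit_r),
      data = list(g_trim)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phenology_estimates", class(out))
  out
}
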