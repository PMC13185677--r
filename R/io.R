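#' Read a survey table of embryo-score counts
#'
#' Reads a CSV with one row per site visit and columns
#' `site,date,s0,s1,s2,s3,s4,s4b,s5`, the per-visit counts of adults in each
#' embryo score class. Proportions are computed per visit as
#' fertilized / total, which normalizes for visits when the target sample
#' size could not be collected.
#'
#' @param path Path to a CSV file.
#' @param max_n Maximum plausible per-visit sample size (default 100, the
#'   study design's target). Rows exceeding it are a validation error.
#' @return A tibble with columns `site`, `date` (Date), the seven score-count
#'   columns, and derived `n`, `n_fertilized`, `n_late`, `p_fertilized`.
#'   Rows whose counts sum to zero are dropped with a warning.
#' @export
read_survey_table <- function(path, max_n = 100) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(),
    date = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (nrow(raw) == 0) {
    return(empty_survey_tbl())
  }
  missing <- setdiff(c("site", "date", score_cols()), names(raw))
  if (length(missing) > 0) {
    abort(paste0("survey table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    abort(sprintf("malformed date '%s' in survey row %d", raw$date[bad], bad))
  }
  counts <- as.matrix(raw[score_cols()])
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(apply(counts, 1, function(r) anyNA(r) || any(r < 0) || any(r != round(r))))[1]
    abort(sprintf("invalid count in survey row %d: counts must be non-negative integers", bad))
  }
  tot <- rowSums(counts)
  if (any(tot > max_n)) {
    bad <- which(tot > max_n)[1]
    abort(sprintf("survey row %d has %d adults, exceeding max_n = %d",
                  bad, tot[bad], max_n))
  }
  if (any(tot == 0)) {
    warn(sprintf("dropping %d survey row(s) with zero total count", sum(tot == 0)))
  }
  out <- tibble::as_tibble(raw[c("site", score_cols())])
  out$date <- dates
  out <- out[tot > 0, c("site", "date", score_cols())]
  finalize_survey_tbl(out)
}

empty_survey_tbl <- function() {
  cols <- c(list(site = character(), date = as.Date(character())),
            setNames(rep(list(double()), 7), score_cols()),
            list(n = double(), n_fertilized = double(), n_late = double(),
                 p_fertilized = double()))
  tibble::as_tibble(cols)
}

finalize_survey_tbl <- function(tbl) {
  counts <- as.matrix(tbl[score_cols()])
  tbl$n <- rowSums(counts)
  tbl$n_fertilized <- rowSums(counts[, fertilized_cols(), drop = FALSE])
  tbl$n_late <- rowSums(counts[, late_cols(), drop = FALSE])
  tbl$p_fertilized <- tbl$n_fertilized / tbl$n
  tbl
}

#' Write a survey table
#'
#' Inverse of [read_survey_table()]: writes the count columns at full
#' precision so a write/read round trip is exact.
#'
#' @param surveys Survey tibble (derived columns are dropped on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(surveys, path) {
  readr::write_csv(surveys[c("site", "date", score_cols())], path)
  invisible(path)
}

#' Read an intertidal temperature series
#'
#' Reads a CSV with columns `timestamp` (ISO-8601, treated as UTC or one
#' declared fixed offset) and `temp_c`. Duplicate timestamps are collapsed
#' by their mean with a warning; timestamps out of order after
#' deduplication are an error.
#'
#' @param path Path to a CSV file.
#' @param tz Timezone applied to the timestamps (one fixed offset; default
#'   `"UTC"`).
#' @return A tibble with `timestamp` (POSIXct) and `temp_c`.
#' @export
read_temperature_csv <- function(path, tz = "UTC") {
  raw <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(),
    temp_c = readr::col_double()
  ), progress = FALSE)
  ts <- as.POSIXct(raw$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    abort(sprintf("malformed timestamp '%s' in temperature row %d",
                  raw$timestamp[bad], bad))
  }
  out <- tibble::tibble(timestamp = ts, temp_c = raw$temp_c)
  if (anyDuplicated(out$timestamp)) {
    warn("duplicate timestamps collapsed by mean")
    out <- out |>
      dplyr::group_by(.data$timestamp) |>
      dplyr::summarise(temp_c = mean(.data$temp_c), .groups = "drop")
    # group_by sorts; re-check against the original first occurrences
    first_seen <- ts[!duplicated(ts)]
    if (any(diff(as.numeric(first_seen)) <= 0)) {
      abort("temperature timestamps are not increasing after deduplication")
    }
  } else if (nrow(out) > 1 && any(diff(as.numeric(out$timestamp)) <= 0)) {
    abort("temperature timestamps are not increasing")
  }
  out
}

#' Write a temperature series
#'
#' @param temps Tibble with `timestamp` and `temp_c`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(temps, path) {
  out <- tibble::tibble(
    timestamp = format(temps$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temp_c = temps$temp_c
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write per-season phenology results
#'
#' Serializes the output of [estimate_phenology()] (one row per site-season)
#' to CSV with calendar dates for F50 and LR50.
#'
#' @param estimates Phenology estimate tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(estimates, path) {
  out <- tibble::tibble(
    site = estimates$site,
    season = estimates$season,
    f50_date = format(day_index_to_date(estimates$f50, estimates$start_year)),
    lr50_date = format(day_index_to_date(estimates$lr50, estimates$start_year)),
    duration_days = estimates$duration_days,
    f50_valid = estimates$f50_valid,
    flags = vapply(estimates$flags, paste, character(1), collapse = ";")
  )
  readr::write_csv(out, path)
  invisible(path)
}
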