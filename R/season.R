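#' Map survey observations onto a within-season day axis
#'
#' Reproductive seasons straddle the New Year (fertilization in fall, larval
#' release in winter or spring), so fitting needs one continuous time axis.
#' Each observation is assigned to the season whose start (Sep 1 by default)
#' most recently precedes it, and `day_index` counts days since that start.
#'
#' @param surveys Survey tibble from [read_survey_table()] (or any tibble
#'   with `site`, `date`, `n`, `n_fertilized`, `n_late` columns).
#' @param season_start Month-day string `"MM-DD"` marking the season
#'   boundary. Default `"09-01"`.
#' @return A brooding-series tibble with one row per visit: `site`,
#'   `start_year`, `season` (label like `"2021-2022"`), `date`, `day_index`,
#'   `n`, `n_fertilized`, `n_late`, `p_raw`. Sorted by site, season, day.
#' @examples
#' obs <- tibble::tibble(
#'   site = "HFX", date = as.Date(c("2021-10-15", "2022-03-01")),
#'   n = c(100, 90), n_fertilized = c(10, 80), n_late = c(0, 40)
#' )
#' to_season_axis(obs)
#' @export
to_season_axis <- function(surveys, season_start = "09-01") {
  if (nrow(surveys) == 0) {
    return(tibble::tibble(
      site = character(), start_year = integer(), season = character(),
      date = as.Date(character()), day_index = double(), n = double(),
      n_fertilized = double(), n_late = double(), p_raw = double()
    ))
  }
  yr <- as.integer(format(surveys$date, "%Y"))
  boundary <- as.Date(paste0(yr, "-", season_start))
  start_year <- ifelse(surveys$date >= boundary, yr, yr - 1L)
  season_origin <- as.Date(paste0(start_year, "-", season_start))
  day_index <- as.numeric(surveys$date - season_origin)
  stopifnot(all(day_index >= 0), all(day_index <= 366))
  tibble::tibble(
    site = surveys$site,
    start_year = as.integer(start_year),
    season = paste0(start_year, "-", start_year + 1L),
    date = surveys$date,
    day_index = day_index,
    n = surveys$n,
    n_fertilized = surveys$n_fertilized,
    n_late = surveys$n_late,
    p_raw = surveys$n_fertilized / surveys$n
  ) |>
    dplyr::arrange(.data$site, .data$start_year, .data$day_index)
}

#' Convert a within-season day index back to a calendar date
#'
#' @param day_index Numeric days since the season start (fractional values
#'   are rounded to the nearest day).
#' @param start_year Season start year(s).
#' @param season_start Month-day string of the season boundary.
#' @return A Date vector.
#' @export
day_index_to_date <- function(day_index, start_year, season_start = "09-01") {
  origin <- as.Date(paste0(start_year, "-", season_start))
  origin + round(day_index)
}

#' Convert a calendar month-day within a season to a day index
#'
#' Month-days from September through December fall in the season's start
#' year; January through August fall in the following year.
#'
#' @param month_day Month-day string `"MM-DD"`.
#' @param season_start Month-day string of the season boundary.
#' @return Integer day index relative to the season start.
#' @export
season_day <- function(month_day, season_start = "09-01") {
  y0 <- 2001L # arbitrary non-leap reference year
  origin <- as.Date(paste0(y0, "-", season_start))
  d <- as.Date(paste0(y0, "-", month_day))
  sel <- d < origin
  if (any(sel)) {
    d[sel] <- as.Date(paste0(y0 + 1L, "-", month_day[sel]))
  }
  as.integer(d - origin)
}
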