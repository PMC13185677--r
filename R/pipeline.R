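#' Run the full phenology-and-temperature analysis
#'
#' End-to-end orchestration: map surveys onto season axes and estimate
#' per-site-season phenology (F50, LR50, duration); regularize and PL64-
#' filter each season's temperature series; summarize fall (Sep 22 --
#' Dec 22) means, early-fall (Sep 22 -- Nov 20) subzero flags, and mean
#' temperature over each brooding window; then fit the two inference
#' models. Seasons with an unusable F50 (earliest scaled value >= 60%)
#' keep their LR50 and duration but are skipped, with a logged reason, when
#' building the anomaly regression; seasons with subzero early falls enter
#' the anomaly records but are excluded from that regression. The analysis
#' path is fully deterministic.
#'
#' @param surveys Survey tibble ([read_survey_table()] layout with derived
#'   columns).
#' @param temperatures Tibble with `site`, `timestamp`, `temp_c` and
#'   optionally `start_year`; derived from the Sep-1 season boundary when
#'   absent.
#' @param threshold,f50_valid_max,weights,exclude_windows Passed to
#'   [estimate_phenology()].
#' @return A list of class `brood_study_results` with elements `phenology`
#'   (per-season estimates), `thermal` (per-season temperature summary),
#'   `anomalies`, `f50_model`, `duration_model`, and `log` (the recorded
#'   exclusions, each named by the governing rule).
#' @export
run_study <- function(surveys, temperatures, threshold = 0.95,
                      f50_valid_max = 0.60, weights = "none",
                      exclude_windows = NULL) {
  series <- to_season_axis(surveys)
  estimates <- estimate_phenology(series, threshold = threshold,
                                  f50_valid_max = f50_valid_max,
                                  weights = weights,
                                  exclude_windows = exclude_windows)
  if (!"start_year" %in% names(temperatures)) {
    yr <- as.integer(format(temperatures$timestamp, "%Y"))
    mo <- as.integer(format(temperatures$timestamp, "%m"))
    temperatures$start_year <- ifelse(mo >= 9, yr, yr - 1L)
  }
  log_lines <- character()
  note <- function(rule, what) {
    line <- sprintf("[%s] %s", rule, what)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  thermal <- purrr::pmap(
    estimates[c("site", "start_year", "season", "f50", "lr50", "f50_valid")],
    function(site, start_year, season, f50, lr50, f50_valid) {
      sel <- temperatures$site == site & temperatures$start_year == start_year
      if (!any(sel)) {
        abort(sprintf("no temperature series for %s %s", site, season))
      }
      filt <- pl64_filter(regularize_hourly(
        temperatures[sel, c("timestamp", "temp_c")]))
      win <- season_windows(start_year)
      origin <- as.POSIXct(sprintf("%d-09-01 00:00:00", start_year), tz = "UTC")
      tibble::tibble(
        site = site, start_year = start_year, season = season,
        fall_temp_mean = window_mean(filt, win$fall[1], win$fall[2]),
        subzero_early_fall = detect_subzero(filt, win$early_fall),
        brooding_temp_mean = window_mean(filt, origin + f50 * 86400,
                                         origin + lr50 * 86400)
      )
    }) |> dplyr::bind_rows()

  merged <- dplyr::left_join(
    estimates[c("site", "start_year", "season", "f50", "lr50",
                "duration_days", "f50_valid")],
    thermal, by = c("site", "start_year", "season")
  )

  for (k in which(!merged$f50_valid)) {
    note("f50-validity", sprintf(
      "%s %s: earliest scaled value >= %.0f%%, F50 withheld from anomaly model (LR50/duration kept)",
      merged$site[k], merged$season[k], 100 * f50_valid_max))
  }
  anom_in <- merged[merged$f50_valid, ]
  n_by_site <- table(anom_in$site)
  thin <- names(n_by_site)[n_by_site < 2]
  for (s in thin) {
    note("anomaly-min-seasons",
         sprintf("%s: fewer than 2 seasons with valid F50, site dropped from anomaly model", s))
  }
  anom_in <- anom_in[!anom_in$site %in% thin, ]
  anomalies <- if (nrow(anom_in) > 0) compute_anomalies(anom_in) else NULL

  f50_model <- NULL
  if (!is.null(anomalies)) {
    for (k in which(anomalies$subzero_early_fall)) {
      note("subzero-exclusion", sprintf(
        "%s %s: subzero filtered temperatures in early fall, excluded from anomaly regression",
        anomalies$site[k], anomalies$season[k]))
    }
    if (sum(!anomalies$subzero_early_fall) >= 3) {
      f50_model <- fit_f50_anomaly_model(anomalies)
    } else {
      note("anomaly-min-n", "fewer than 3 records after subzero exclusion, anomaly model not fit")
    }
  }

  dur_in <- merged[is.finite(merged$duration_days) &
                     is.finite(merged$brooding_temp_mean), ]
  duration_model <- if (nrow(dur_in) >= 3) {
    fit_duration_model(dur_in$duration_days, dur_in$brooding_temp_mean,
                       data = dur_in)
  } else NULL

  structure(list(
    phenology = estimates, thermal = thermal, anomalies = anomalies,
    f50_model = f50_model, duration_model = duration_model, log = log_lines
  ), class = "brood_study_results")
}

#' Run the analysis from an on-disk study and write a results bundle
#'
#' Reads a study directory in the [write_sim_study()] layout
#' (`surveys.csv`, `temps_<site>_<year>.csv`), runs [run_study()], and
#' writes the per-season results CSV, the thermal summary CSV, both
#' regression reports as JSON, a markdown report, and a run manifest
#' (configuration snapshot, input digests, package version, timestamp).
#'
#' @param study_dir Input directory.
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [run_study()].
#' @return The `brood_study_results` bundle, invisibly.
#' @export
run_study_dir <- function(study_dir, out_dir, ...) {
  study <- read_sim_study(study_dir)
  res <- run_study(study$surveys, study$temperatures, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est <- res$phenology
  write_results_csv(est, file.path(out_dir, "phenology.csv"))
  readr::write_csv(res$thermal, file.path(out_dir, "thermal_summary.csv"))
  models <- list(
    f50_anomaly = if (!is.null(res$f50_model)) as.list(glance(res$f50_model)),
    duration = if (!is.null(res$duration_model)) as.list(glance(res$duration_model))
  )
  jsonlite::write_json(models, file.path(out_dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report_study(res), file.path(out_dir, "report.md"))
  inputs <- list.files(study_dir, full.names = TRUE, pattern = "\\.csv$")
  manifest <- list(
    package = "broodr",
    version = as.character(utils::packageVersion("broodr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    arguments = lapply(list(...), function(x) if (is.atomic(x)) x else "object"),
    inputs = as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(res)
}

#' Human-readable study report
#'
#' Markdown summary of every site-season (calendar F50/LR50 dates,
#' duration, flags) and the two regression tables, plus the exclusion log.
#'
#' @param results A `brood_study_results` bundle.
#' @return Character vector of markdown lines.
#' @export
report_study <- function(results) {
  est <- results$phenology
  th <- results$thermal
  lines <- c("# Brooding phenology report", "",
             "## Site-season estimates", "",
             "| site | season | F50 | LR50 | duration (d) | F50 usable | flags |",
             "|------|--------|-----|------|--------------|------------|-------|")
  for (k in seq_len(nrow(est))) {
    flags <- est$flags[[k]]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %.1f | %s | %s |",
      est$site[k], est$season[k],
      format(day_index_to_date(est$f50[k], est$start_year[k]), "%b %d"),
      format(day_index_to_date(est$lr50[k], est$start_year[k]), "%b %d"),
      est$duration_days[k],
      ifelse(est$f50_valid[k], "yes", "no"),
      if (length(flags)) paste(flags, collapse = ";") else "-"
    ))
  }
  fmt_model <- function(m, label, units) {
    if (is.null(m)) return(c(sprintf("## %s", label), "", "not fit", ""))
    c(sprintf("## %s", label), "",
      sprintf("slope %.3f %s (95%% CI %.3f to %.3f); F(%d,%d) = %.2f; R2 = %.3f; p = %.4g; n = %d%s",
              m$slope, units, m$slope_ci95[1], m$slope_ci95[2],
              m$df[1], m$df[2], m$f_stat, m$r2, m$p_value, m$n_used,
              if (m$n_excluded > 0)
                sprintf(" (excluded: %s)", paste(m$excluded_ids, collapse = ", "))
              else ""), "")
  }
  lines <- c(lines, "",
             fmt_model(results$f50_model,
                       "F50 anomaly vs fall temperature anomaly", "d/degC"),
             fmt_model(results$duration_model,
                       "ln(brooding duration) vs mean brooding temperature",
                       "per degC"))
  if (length(results$log)) {
    lines <- c(lines, "## Exclusions and skips", "", results$log, "")
  }
  lines
}

#' @export
print.brood_study_results <- function(x, ...) {
  cat(sprintf("<brood_study_results: %d site-season(s)>\n", nrow(x$phenology)))
  if (!is.null(x$f50_model)) {
    cat(sprintf("  F50 anomaly slope: %.2f d/degC (n = %d, %d excluded)\n",
                x$f50_model$slope, x$f50_model$n_used, x$f50_model$n_excluded))
  }
  if (!is.null(x$duration_model)) {
    cat(sprintf("  duration-law slope: %.3f per degC (R2 = %.2f)\n",
                x$duration_model$slope, x$duration_model$r2))
  }
  invisible(x)
}
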