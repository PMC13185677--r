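#' Simple linear regression with the diagnostics reported downstream
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], repackaged as a
#' one-row summary with the quantities the two phenology models report:
#' slope and intercept, 95% t-based confidence interval for the slope,
#' R-squared, the F statistic on (1, n-2) degrees of freedom and its
#' p-value.
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` not constant.
#' @param data Optional tibble the observations came from; retained for
#'   [augment()]-style inspection.
#' @return An object of class `pheno_lm` wrapping the `lm` fit plus the
#'   summary row; supports [tidy()], [glance()], `predict()` and `print()`.
#' @export
ols <- function(x, y, data = NULL) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("at least 3 observations are required")
  if (diff(range(x)) == 0) abort("x is constant: slope undefined")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  s <- summary(fit)
  ci <- confint(fit, "x", level = 0.95)
  if (sd(y) == 0) {
    # y carries no variance: slope exactly 0, nothing explained
    r2 <- 0
    f_stat <- 0
    p_value <- 1
  } else {
    r2 <- s$r.squared
    f_stat <- unname(s$fstatistic[1])
    p_value <- unname(pf(f_stat, 1, length(x) - 2, lower.tail = FALSE))
  }
  new_pheno_lm(
    fit = fit,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    slope_ci95 = c(ci[1], ci[2]),
    r2 = r2,
    f_stat = f_stat,
    df = c(1L, length(x) - 2L),
    p_value = p_value,
    n_used = length(x), n_excluded = 0L, excluded_ids = character(),
    data = data
  )
}

new_pheno_lm <- function(..., subclass = character()) {
  structure(list(...), class = c(subclass, "pheno_lm"))
}

#' Regress F50 anomalies on fall temperature anomalies
#'
#' The first headline model: within-site interannual variation in
#' fertilization timing as a function of fall (Sep 22 -- Dec 22) intertidal
#' temperature anomalies. Seasons whose filtered early-fall series included
#' subzero temperatures are excluded before fitting, because freezing may
#' independently delay fertilization; sites are pooled, anomalies being
#' already site-centered. A positive slope (days per deg C) means a warmer
#' fall delays fertilization.
#'
#' @param records Anomaly tibble from [compute_anomalies()] (columns
#'   `site`, `season`, `fall_temp_anomaly`, `f50_anomaly`,
#'   `subzero_early_fall`).
#' @return A `pheno_lm` (subclass `f50_anomaly_lm`) with `n_excluded` and
#'   `excluded_ids` recording the subzero exclusions.
#' @export
fit_f50_anomaly_model <- function(records) {
  excl <- records$subzero_early_fall
  kept <- records[!excl, ]
  if (nrow(kept) < 3) {
    abort(sprintf("only %d record(s) left after excluding subzero seasons (%s)",
                  nrow(kept),
                  paste(records$site[excl], records$season[excl],
                        sep = " ", collapse = ", ")))
  }
  out <- ols(kept$fall_temp_anomaly, kept$f50_anomaly, data = kept)
  out$n_excluded <- sum(excl)
  out$excluded_ids <- paste(records$site[excl], records$season[excl])
  class(out) <- c("f50_anomaly_lm", class(out))
  out
}

#' Regress log brooding duration on mean brooding temperature
#'
#' The second headline model: brooding duration decreases exponentially
#' with temperature, so durations are ln-transformed and regressed on the
#' average filtered intertidal temperature between F50 and LR50. The fitted
#' curve is `D(T) = exp(intercept + slope * T)`, guaranteed positive on the
#' response scale.
#'
#' @param durations Brooding durations in days (strictly positive).
#' @param mean_temps Mean filtered intertidal temperature over each
#'   brooding window, deg C.
#' @param data Optional source tibble, carried for inspection.
#' @return A `pheno_lm` (subclass `duration_lm`); `predict()` on it returns
#'   durations in days.
#' @export
fit_duration_model <- function(durations, mean_temps, data = NULL) {
  if (any(durations <= 0)) abort("durations must be strictly positive")
  out <- ols(mean_temps, log(durations), data = data)
  class(out) <- c("duration_lm", class(out))
  out
}

#' @export
predict.duration_lm <- function(object, newdata = NULL, ...) {
  temps <- if (is.null(newdata)) object$fit$model$x else newdata
  exp(object$intercept + object$slope * temps)
}

#' @export
print.pheno_lm <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  cat(sprintf("  slope %.4g (95%% CI %.4g to %.4g), intercept %.4g\n",
              x$slope, x$slope_ci95[1], x$slope_ci95[2], x$intercept))
  cat(sprintf("  F(%d,%d) = %.3f, R2 = %.3f, p = %.4g, n = %d",
              x$df[1], x$df[2], x$f_stat, x$r2, x$p_value, x$n_used))
  if (x$n_excluded > 0) {
    cat(sprintf(" (%d excluded: %s)", x$n_excluded,
                paste(x$excluded_ids, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.pheno_lm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @export
glance.pheno_lm <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    ci_low = x$slope_ci95[1], ci_high = x$slope_ci95[2],
    r.squared = x$r2, statistic = x$f_stat,
    df = x$df[1], df.residual = x$df[2], p.value = x$p_value,
    n_used = x$n_used, n_excluded = x$n_excluded
  )
}
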