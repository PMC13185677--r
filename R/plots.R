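#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_vline
#'   facet_wrap labs theme_minimal geom_smooth scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Plot scaled brooding series with their fitted logistic curves
#'
#' One panel per site-season: scaled fertilized proportions, the fitted
#' fertilization (rising) and release (falling) curves, and dashed lines at
#' F50 and LR50.
#'
#' @param object A `phenology_estimates` tibble from [estimate_phenology()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phenology_estimates <- function(object, ...) {
  pts <- purrr::map2(object$data, seq_len(nrow(object)), function(d, k) {
    dplyr::mutate(d, panel = paste(object$site[k], object$season[k]))
  }) |> dplyr::bind_rows()
  curves <- purrr::map(seq_len(nrow(object)), function(k) {
    grid_one <- function(fit, limb) {
      days <- seq(min(fit$days), max(fit$days), length.out = 100)
      tibble::tibble(
        panel = paste(object$site[k], object$season[k]),
        day_index = days, limb = limb,
        p = plogis(fit$beta0 + fit$beta1 * days)
      )
    }
    dplyr::bind_rows(grid_one(object$fit_fert[[k]], "fertilization"),
                     grid_one(object$fit_rel[[k]], "release"))
  }) |> dplyr::bind_rows()
  mids <- tibble::tibble(
    panel = paste(object$site, object$season),
    f50 = object$f50, lr50 = object$lr50
  )
  ggplot(pts, aes(x = .data$day_index, y = .data$p_scaled)) +
    geom_point(size = 1.2) +
    geom_line(data = curves, aes(y = .data$p, color = .data$limb)) +
    geom_vline(data = mids, aes(xintercept = .data$f50),
               linetype = "dashed", color = "steelblue") +
    geom_vline(data = mids, aes(xintercept = .data$lr50),
               linetype = "dashed", color = "seagreen") +
    facet_wrap(~panel) +
    labs(x = "days since Sep 1", y = "scaled brooding proportion",
         color = NULL) +
    theme_minimal()
}

#' Plot a fitted phenology regression
#'
#' Scatter of the model's observations with the least-squares line and 95%
#' confidence band. For the duration model the response axis shows days on
#' a log scale.
#'
#' @param object A `pheno_lm` from [ols()], [fit_f50_anomaly_model()] or
#'   [fit_duration_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pheno_lm <- function(object, ...) {
  df <- object$fit$model
  is_dur <- inherits(object, "duration_lm")
  lab <- if (inherits(object, "f50_anomaly_lm")) {
    labs(x = "fall temperature anomaly (degC)", y = "F50 anomaly (days)")
  } else if (is_dur) {
    labs(x = "mean brooding temperature (degC)", y = "brooding duration (days)")
  } else {
    labs(x = "x", y = "y")
  }
  p <- ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, color = "steelblue") +
    lab + theme_minimal()
  if (is_dur) {
    brk <- pretty(exp(df$y))
    p <- p + scale_y_continuous(breaks = log(brk[brk > 0]),
                                labels = brk[brk > 0])
  }
  p
}

#' Plot a temperature series, optionally against its filtered version
#'
#' @param temps Hourly temperature tibble (unfiltered).
#' @param filtered Optional filtered tibble from [pl64_filter()].
#' @return A ggplot.
#' @export
plot_temperature <- function(temps, filtered = NULL) {
  p <- ggplot(temps, aes(x = .data$timestamp, y = .data$temp_c)) +
    geom_line(alpha = 0.35) +
    labs(x = NULL, y = "temperature (degC)") +
    theme_minimal()
  if (!is.null(filtered)) {
    p <- p + geom_line(data = filtered, color = "firebrick")
  }
  p
}
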