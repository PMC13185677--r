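# Independent oracles used across the suite. These deliberately avoid the
# package's own fitting code paths: brute-force grid refinement over the
# objective surfaces.

binom_deviance <- function(days, p, b0, b1, weights = rep(1, length(p))) {
  mu <- pmin(pmax(plogis(b0 + b1 * days), 1e-12), 1 - 1e-12)
  t1 <- ifelse(p > 0, p * log(p / mu), 0)
  t2 <- ifelse(p < 1, (1 - p) * log((1 - p) / (1 - mu)), 0)
  2 * sum(weights * (t1 + t2))
}

# coarse-to-fine 2-D grid search minimizing the binomial deviance; the
# search runs on centered days (intercept = logit at the mean day) so the
# objective surface is well conditioned, then maps back
grid_fit_logistic <- function(days, p, c0_range = c(-40, 40),
                              b1_range = c(-3, 3), rounds = 10, n = 41) {
  mid <- mean(days)
  dc <- days - mid
  for (r in seq_len(rounds)) {
    c0s <- seq(c0_range[1], c0_range[2], length.out = n)
    b1s <- seq(b1_range[1], b1_range[2], length.out = n)
    g <- expand.grid(c0 = c0s, b1 = b1s)
    d <- vapply(seq_len(nrow(g)),
                function(i) binom_deviance(dc, p, g$c0[i], g$b1[i]),
                numeric(1))
    best <- g[which.min(d), ]
    step0 <- diff(c0_range) / (n - 1)
    step1 <- diff(b1_range) / (n - 1)
    c0_range <- c(best$c0 - 2 * step0, best$c0 + 2 * step0)
    b1_range <- c(best$b1 - 2 * step1, best$b1 + 2 * step1)
  }
  c(b0 = best$c0 - best$b1 * mid, b1 = best$b1)
}

# coarse-to-fine 2-D grid search minimizing the residual sum of squares
grid_fit_ols <- function(x, y, rounds = 12, n = 41) {
  a_range <- range(y) + c(-1, 1) * diff(range(y))
  b_max <- 4 * diff(range(y)) / diff(range(x))
  b_range <- c(-b_max, b_max)
  for (r in seq_len(rounds)) {
    as <- seq(a_range[1], a_range[2], length.out = n)
    bs <- seq(b_range[1], b_range[2], length.out = n)
    g <- expand.grid(a = as, b = bs)
    sse <- vapply(seq_len(nrow(g)),
                  function(i) sum((y - g$a[i] - g$b[i] * x)^2), numeric(1))
    best <- g[which.min(sse), ]
    step_a <- diff(a_range) / (n - 1)
    step_b <- diff(b_range) / (n - 1)
    a_range <- c(best$a - 2 * step_a, best$a + 2 * step_a)
    b_range <- c(best$b - 2 * step_b, best$b + 2 * step_b)
  }
  c(intercept = best$a, slope = best$b)
}

# brooding series straight from vectors, for unit tests
make_series <- function(days, p_raw, n = 100, site = "A", start_year = 2021,
                        n_late = rep(0, length(days))) {
  tibble::tibble(
    site = site, start_year = start_year,
    season = paste0(start_year, "-", start_year + 1),
    date = as.Date(paste0(start_year, "-09-01")) + days,
    day_index = as.numeric(days), n = n,
    n_fertilized = round(p_raw * n), n_late = n_late,
    p_raw = p_raw
  )
}

# hourly temperature tibble from a numeric vector
make_temps <- function(values, start = "2021-09-01 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(timestamp = t0 + 3600 * (seq_along(values) - 1),
                 temp_c = values)
}
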