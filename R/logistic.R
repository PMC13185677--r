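#' Fit a two-parameter logistic curve to scaled brooding proportions
#'
#' Fits `logit(p) = beta0 + beta1 * day` by iteratively reweighted least
#' squares, maximizing the binomial quasi-likelihood. Point estimates are
#' identical to a binomial GLM; the quasi-binomial dispersion affects only
#' the reported standard errors, which are not used downstream. Visits are
#' unweighted by default (each contributes one proportion); per-visit
#' sample-size weights are available via `weights`.
#'
#' Degenerate inputs are handled explicitly rather than left to fail:
#' a flat series (all proportions equal) is flagged `degenerate`, and
#' perfectly separated series (deviance collapsing to zero with
#' `|beta1| > 50` logit/day) are flagged `separation` with capped
#' coefficients and a stored bracket midpoint so that downstream midpoint
#' estimation never crashes on step-like data.
#'
#' @param days Numeric day-index vector (at least 3 values).
#' @param p Proportions in `[0, 1]` (scaled brooding proportions).
#' @param direction `"rising"` for the fertilization limb or `"falling"`
#'   for the larval-release limb; used for sanity flags only, the sign of
#'   `beta1` is estimated from the data.
#' @param weights Optional non-negative per-visit weights (e.g. sample
#'   sizes). Default: all 1.
#' @param max_iter,tol IRLS controls: at most `max_iter` iterations,
#'   convergence when the deviance changes by less than `tol`.
#' @return An object of class `logistic_fit`: a list with `beta0`, `beta1`,
#'   `direction`, `converged`, `n_iter`, `deviance`, `dispersion`,
#'   `se_beta0`, `se_beta1`, `separation`, `degenerate`, `bracket_midpoint`,
#'   `n`, and the input data. Supports [tidy()], [glance()] and
#'   [estimate_midpoint()].
#' @export
fit_logistic <- function(days, p, direction = c("rising", "falling"),
                         weights = NULL, max_iter = 100, tol = 1e-8) {
  direction <- arg_match(direction)
  if (length(days) != length(p)) abort("days and p must have equal length")
  if (length(days) < 3) abort("at least 3 observations are required")
  if (any(p < 0 | p > 1)) abort("proportions must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(days))
  if (any(weights < 0)) abort("weights must be non-negative")

  mu_min <- 1e-9
  dev_fun <- function(mu) {
    # binomial deviance for proportion data; 0*log(0) := 0
    t1 <- ifelse(p > 0, p * log(p / mu), 0)
    t2 <- ifelse(p < 1, (1 - p) * log((1 - p) / (1 - mu)), 0)
    2 * sum(weights * (t1 + t2))
  }

  if (diff(range(p)) == 0) {
    # flat series: beta1 = 0 exactly, no midpoint
    b0 <- qlogis(min(max(p[1], mu_min), 1 - mu_min))
    fit <- new_logistic_fit(
      beta0 = b0, beta1 = 0, direction = direction, converged = TRUE,
      n_iter = 0L, deviance = dev_fun(rep(plogis(b0), length(p))),
      dispersion = NA_real_, se_beta0 = NA_real_, se_beta1 = NA_real_,
      separation = FALSE, degenerate = TRUE, bracket_midpoint = NA_real_,
      days = days, p = p, weights = weights
    )
    return(fit)
  }

  beta <- c(qlogis(min(max(mean(p), 0.05), 0.95)), 0)
  dev <- Inf
  converged <- FALSE
  iter <- 0L
  X <- cbind(1, days)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(plogis(eta), mu_min), 1 - mu_min)
    v <- mu * (1 - mu)
    z <- eta + (p - mu) / v
    w <- weights * v
    fit_ls <- lm.wfit(X, z, w)
    beta <- fit_ls$coefficients
    if (anyNA(beta)) abort("IRLS failed: singular design (constant days?)")
    dev_new <- dev_fun(pmin(pmax(plogis(drop(X %*% beta)), mu_min), 1 - mu_min))
    if (is.finite(dev) && abs(dev - dev_new) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }

  # Perfect separation: all observed proportions are extreme (0/1) and the
  # deviance collapses to zero, so the slope diverges (IRLS would push
  # |beta1| past 50 logit/day given enough iterations). Cap and flag.
  separation <- FALSE
  bracket <- NA_real_
  all_extreme <- all(p <= 1e-12 | p >= 1 - 1e-12)
  if (abs(beta[2]) > 50 || (dev < 1e-6 && all_extreme)) {
    separation <- TRUE
    bracket <- bracket_midpoint(days, p)
    # cap the slope, anchor the intercept at the bracket midpoint
    b1 <- sign(beta[2]) * 50
    beta <- c(-b1 * bracket, b1)
  }

  # quasi-binomial dispersion from Pearson residuals
  mu <- pmin(pmax(plogis(drop(X %*% beta)), mu_min), 1 - mu_min)
  n_par <- 2L
  df_res <- length(p) - n_par
  disp <- if (df_res > 0 && !separation) {
    sum(weights * (p - mu)^2 / (mu * (1 - mu))) / df_res
  } else NA_real_
  se <- rep(NA_real_, 2)
  if (!separation && !is.na(disp)) {
    W <- weights * mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(W))
    cov_b <- tryCatch(disp * solve(XtWX), error = function(e) NULL)
    if (!is.null(cov_b)) se <- sqrt(diag(cov_b))
  }

  new_logistic_fit(
    beta0 = unname(beta[1]), beta1 = unname(beta[2]), direction = direction,
    converged = converged, n_iter = iter, deviance = dev, dispersion = disp,
    se_beta0 = se[1], se_beta1 = se[2], separation = separation,
    degenerate = FALSE, bracket_midpoint = bracket,
    days = days, p = p, weights = weights
  )
}

new_logistic_fit <- function(...) {
  structure(list(...), class = "logistic_fit")
}

# midpoint of the bracketing observations around p = 0.5 for separated data
bracket_midpoint <- function(days, p) {
  o <- order(days)
  days <- days[o]; p <- p[o]
  below <- p < 0.5
  above <- p > 0.5
  if (!any(below) || !any(above)) return(stats::median(days))
  if (which(above)[1] > which(below)[length(which(below))]) {
    # rising: last low day, first high day
    (max(days[below]) + min(days[above])) / 2
  } else {
    # falling: last high day, first low day
    (max(days[above]) + min(days[below])) / 2
  }
}

#' Estimate the day at which the fitted curve crosses 50%
#'
#' For a non-degenerate logistic fit the 50% crossing is `-beta0 / beta1`
#' (in day-index units). For a perfectly separated fit the midpoint of the
#' bracketing observation days is returned instead, carrying the
#' `separation` flag on the fit.
#'
#' @param fit A `logistic_fit` object.
#' @return The midpoint day index (a real number).
#' @export
estimate_midpoint <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (isTRUE(fit$degenerate)) {
    abort("degenerate fit (flat series): the 50% crossing is undefined")
  }
  if (isTRUE(fit$separation)) return(fit$bracket_midpoint)
  -fit$beta0 / fit$beta1
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: %s limb, n = %d>\n", x$direction, length(x$days)))
  cat(sprintf("  logit(p) = %.4f + %.4f * day\n", x$beta0, x$beta1))
  mid <- if (x$degenerate) NA_real_ else estimate_midpoint(x)
  cat(sprintf("  50%% crossing: day %.2f | deviance %.4g | %s\n",
              mid, x$deviance,
              if (x$separation) "SEPARATED" else if (x$degenerate) "DEGENERATE"
              else if (x$converged) sprintf("converged in %d iter", x$n_iter)
              else "NOT converged"))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "day"),
    estimate = c(x$beta0, x$beta1),
    std.error = c(x$se_beta0, x$se_beta1)
  )
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance,
    dispersion = x$dispersion,
    n = length(x$days),
    n_iter = x$n_iter,
    converged = x$converged,
    separation = x$separation,
    degenerate = x$degenerate
  )
}
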