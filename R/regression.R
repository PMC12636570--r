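# ATP production vs growth rate regression -------------------------------

# closed-form OLS used by the bootstrap (avoids lm() overhead)
ols_slope_intercept <- function(x, y) {
  xm <- mean(x)
  ym <- mean(y)
  ssx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / ssx
  c(slope = slope, intercept = ym - slope * xm)
}

#' Fit the linear ATP-growth relationship
#'
#' Ordinary least squares of total ATP production rate on growth rate.
#' The slope (umol ATP per mg protein, per unit hr^-1 of growth) is the
#' apparent ATP cost of synthesizing one mg of cell protein equivalent;
#' the intercept (umol ATP (mg protein)^-1 hr^-1) is the maintenance ATP
#' production rate of a non-dividing cell. The p-value for the Pearson
#' correlation uses the exact t transform `r * sqrt((n-2)/(1-r^2))` with
#' n - 2 degrees of freedom.
#'
#' @param points Data frame with columns `growth_rate` (hr^-1) and
#'   `atp_total` (umol (mg protein)^-1 hr^-1); `n >= 3` and growth rates
#'   not all equal.
#' @return Object of class `line_fit`: `slope`, `intercept`, `pearson_r`,
#'   `r_squared`, `p_value`, `n`, plus the residual standard error
#'   (`sigma`), `x_mean` and `ssx` needed for prediction intervals.
#'   `slope_ci` / `intercept_ci` are `NULL` until filled by
#'   [bootstrap_fit()].
#' @export
fit_line <- function(points) {
  check_columns(points, c("growth_rate", "atp_total"), "points")
  x <- points$growth_rate
  y <- points$atp_total
  n <- length(x)
  if (n < 3L) stop("need at least 3 points to fit the line", call. = FALSE)
  if (var(x) == 0) {
    stop("growth rates are all equal; the slope is unidentifiable",
         call. = FALSE)
  }
  ab <- ols_slope_intercept(x, y)
  resid <- y - (ab[["intercept"]] + ab[["slope"]] * x)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  r <- sign(ab[["slope"]]) * sqrt(max(r2, 0))
  p <- if (r2 >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  structure(
    list(
      slope = ab[["slope"]],
      intercept = ab[["intercept"]],
      pearson_r = r,
      r_squared = r2,
      p_value = p,
      n = n,
      sigma = sqrt(ss_res / (n - 2)),
      x_mean = mean(x),
      ssx = sum((x - mean(x))^2),
      slope_ci = NULL,
      intercept_ci = NULL
    ),
    class = "line_fit"
  )
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf(
    "ATP-growth line: slope = %.4g umol/mg, intercept = %.4g umol/mg/hr\n",
    x$slope, x$intercept
  ))
  cat(sprintf("  r = %.3f, R2 = %.3f, p = %.3g, n = %d\n",
              x$pearson_r, x$r_squared, x$p_value, x$n))
  if (!is.null(x$slope_ci)) {
    cat(sprintf("  95%% bootstrap CI: slope [%.4g, %.4g], intercept [%.4g, %.4g]\n",
                x$slope_ci[1L], x$slope_ci[2L],
                x$intercept_ci[1L], x$intercept_ci[2L]))
  }
  invisible(x)
}

#' Bootstrap confidence intervals for the ATP-growth line
#'
#' Nonparametric case resampling: condition-level (growth, ATP) pairs are
#' resampled with replacement `n_iter` times, the line is refit per
#' resample, and the 2.5th / 97.5th percentiles of the slope and
#' intercept distributions form the interval. Resamples with degenerate
#' (constant) growth rates are redrawn so that exactly `n_iter` estimates
#' enter the percentiles. With `resample = "replicates"` and a
#' `condition` column present, replicate rows are resampled within each
#' condition and the fit uses the resulting condition means.
#'
#' @param points As in [fit_line()]; for replicate-level resampling also
#'   a `condition` column.
#' @param n_iter Bootstrap iterations (default 10000).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param level Confidence level (default 0.95).
#' @param resample `"conditions"` (default) or `"replicates"`.
#' @return The [fit_line()] object for `points` with `slope_ci`,
#'   `intercept_ci`, `n_boot`, `seed` and `n_degenerate_redrawn` filled
#'   in, plus the bootstrap draws in `boot_slopes` / `boot_intercepts`.
#' @export
bootstrap_fit <- function(points, n_iter = 10000, seed = 1, level = 0.95,
                          resample = c("conditions", "replicates")) {
  resample <- match.arg(resample)
  check_number(n_iter, "n_iter", min = 1)
  if (level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  fit <- if (resample == "replicates") {
    check_columns(points, "condition", "points")
    fit_line(condition_means(points))
  } else {
    fit_line(points)
  }
  draws <- with_seed(seed, {
    if (resample == "conditions") {
      boot_case_resample(points$growth_rate, points$atp_total, n_iter)
    } else {
      boot_replicate_resample(points, n_iter)
    }
  })
  alpha <- (1 - level) / 2
  fit$slope_ci <- unname(quantile(draws$slopes, c(alpha, 1 - alpha)))
  fit$intercept_ci <- unname(quantile(draws$intercepts, c(alpha, 1 - alpha)))
  fit$boot_slopes <- draws$slopes
  fit$boot_intercepts <- draws$intercepts
  fit$n_boot <- n_iter
  fit$seed <- seed
  fit$n_degenerate_redrawn <- draws$n_redrawn
  fit
}

# vectorized case-resampling bootstrap; degenerate columns redrawn
boot_case_resample <- function(x, y, n_iter) {
  n <- length(x)
  slopes <- numeric(n_iter)
  intercepts <- numeric(n_iter)
  pending <- seq_len(n_iter)
  n_redrawn <- 0L
  while (length(pending) > 0L) {
    m <- length(pending)
    idx <- matrix(sample.int(n, n * m, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n)
    yb <- matrix(y[idx], nrow = n)
    xm <- colMeans(xb)
    ym <- colMeans(yb)
    ssx <- colSums(xb^2) - n * xm^2
    ok <- ssx > 0
    sl <- (colSums(xb * yb) - n * xm * ym) / ssx
    slopes[pending[ok]] <- sl[ok]
    intercepts[pending[ok]] <- ym[ok] - sl[ok] * xm[ok]
    n_redrawn <- n_redrawn + sum(!ok)
    pending <- pending[!ok]
  }
  list(slopes = slopes, intercepts = intercepts, n_redrawn = n_redrawn)
}

condition_means <- function(points) {
  g <- split(points, points$condition)
  do.call(rbind, lapply(g, function(d) {
    tibble::tibble(growth_rate = mean(d$growth_rate),
                   atp_total = mean(d$atp_total))
  }))
}

boot_replicate_resample <- function(points, n_iter) {
  groups <- split(points, points$condition)
  slopes <- numeric(n_iter)
  intercepts <- numeric(n_iter)
  n_redrawn <- 0L
  i <- 1L
  while (i <= n_iter) {
    means <- vapply(groups, function(d) {
      j <- sample.int(nrow(d), nrow(d), replace = TRUE)
      c(mean(d$growth_rate[j]), mean(d$atp_total[j]))
    }, numeric(2))
    x <- means[1L, ]
    y <- means[2L, ]
    if (var(x) == 0) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    ab <- ols_slope_intercept(x, y)
    slopes[i] <- ab[["slope"]]
    intercepts[i] <- ab[["intercept"]]
    i <- i + 1L
  }
  list(slopes = slopes, intercepts = intercepts, n_redrawn = n_redrawn)
}

#' Prediction band around the fitted ATP-growth line
#'
#' Classical OLS prediction interval for a single future observation,
#' using the t distribution with n - 2 degrees of freedom:
#' `fit +/- t * sigma * sqrt(1 + 1/n + (x - mean(x))^2 / ssx)`. The band
#' is narrowest at the mean growth rate and widens away from it; at
#' `level = 0` it collapses to the fitted line.
#'
#' @param fit A [line_fit][fit_line].
#' @param x Growth rates at which to evaluate the band.
#' @param level Coverage level for future individual observations
#'   (default 0.95); must lie in `[0, 1)`.
#' @return A tibble of class `prediction_band` with columns
#'   `growth_rate`, `fit`, `lower`, `upper`; the fit and level are kept
#'   as attributes so the band can be evaluated at new growth rates.
#' @export
prediction_band <- function(fit, x, level = 0.95) {
  stopifnot(inherits(fit, "line_fit"))
  check_numeric_vector(x, "x")
  if (level < 0 || level >= 1) {
    stop("`level` must be in [0, 1)", call. = FALSE)
  }
  lim <- band_limits(fit, x, level)
  out <- tibble::tibble(growth_rate = x, fit = lim$fit,
                        lower = lim$lower, upper = lim$upper)
  attr(out, "line_fit") <- fit
  attr(out, "level") <- level
  class(out) <- c("prediction_band", class(out))
  out
}

band_limits <- function(fit, x, level) {
  yhat <- fit$intercept + fit$slope * x
  se_pred <- fit$sigma * sqrt(1 + 1 / fit$n + (x - fit$x_mean)^2 / fit$ssx)
  tcrit <- qt(1 - (1 - level) / 2, df = fit$n - 2)
  list(fit = yhat, lower = yhat - tcrit * se_pred, upper = yhat + tcrit * se_pred)
}

#' Classify a measurement against the prediction band
#'
#' Compares one ATP component of a flux-growth point with the band
#' evaluated at that point's growth rate. Points exactly on a bound count
#' as `"inside"`.
#'
#' @param band A [prediction_band()].
#' @param point List or one-row data frame with `growth_rate` and the ATP
#'   components `atp_total`, `atp_glycolytic`, `atp_respiratory` (only
#'   the selected one is required).
#' @param axis Which component to compare: `"total_atp"` (default),
#'   `"glycolytic"` or `"respiratory"`.
#' @return `"inside"`, `"above"` or `"below"`.
#' @export
classify_point <- function(band, point,
                           axis = c("total_atp", "glycolytic", "respiratory")) {
  axis <- match.arg(axis)
  stopifnot(inherits(band, "prediction_band"))
  fit <- attr(band, "line_fit")
  level <- attr(band, "level")
  col <- switch(axis,
    total_atp = "atp_total",
    glycolytic = "atp_glycolytic",
    respiratory = "atp_respiratory"
  )
  value <- point[[col]]
  if (is.null(value) || is.na(value)) {
    stop(sprintf("point lacks the `%s` component", col), call. = FALSE)
  }
  x <- point[["growth_rate"]] %||% point[["growth_rate_per_hr"]]
  if (is.null(x)) {
    stop("point lacks a growth rate", call. = FALSE)
  }
  lim <- band_limits(fit, x, level)
  if (value > lim$upper) "above" else if (value < lim$lower) "below" else "inside"
}
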