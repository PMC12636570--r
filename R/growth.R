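# Exponential growth fitting from microplate nuclei counts ---------------

#' Remove plate edge wells
#'
#' Wells in the first or last row or column of the plate are discarded to
#' avoid evaporation-driven edge effects on growth.
#'
#' @param plate Long-format data frame with at least columns `well_id`,
#'   `row`, `col` (1-based plate coordinates).
#' @param n_rows,n_cols Plate geometry (default 8 x 12, a 96-well plate).
#' @return The interior-well subset of `plate`. Warns (does not error)
#'   when no interior wells exist.
#' @examples
#' # an 8 x 12 plate retains (8 - 2) * (12 - 2) = 60 interior wells
#' @export
filter_edge_wells <- function(plate, n_rows = 8, n_cols = 12) {
  check_columns(plate, c("well_id", "row", "col"), "plate")
  if (any(plate$row < 1 | plate$row > n_rows) ||
      any(plate$col < 1 | plate$col > n_cols)) {
    stop("plate contains wells outside the stated geometry", call. = FALSE)
  }
  keep <- plate$row > 1 & plate$row < n_rows & plate$col > 1 & plate$col < n_cols
  out <- plate[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no interior wells remain after edge filtering", call. = FALSE)
  }
  out
}

#' Exclude wells with improperly low nuclei counts
#'
#' A well whose count falls below `threshold` at any timepoint is excluded
#' from growth-rate estimation; counts that low indicate seeding or
#' segmentation failure. The boundary is strict: a count exactly at the
#' threshold passes.
#'
#' @param plate Long-format data frame with columns `well_id`,
#'   `nuclei_count`.
#' @param threshold Minimum acceptable count (default 100 nuclei).
#' @return `plate` restricted to passing wells, with the excluded well ids
#'   and reasons in attribute `"excluded"` (a tibble `well_id`, `reason`).
#' @export
filter_low_counts <- function(plate, threshold = 100) {
  check_columns(plate, c("well_id", "nuclei_count"), "plate")
  check_number(threshold, "threshold", min = 0)
  bad <- unique(plate$well_id[plate$nuclei_count < threshold])
  out <- plate[!(plate$well_id %in% bad), , drop = FALSE]
  attr(out, "excluded") <- tibble::tibble(
    well_id = bad,
    reason = sprintf("nuclei count below %g at >= 1 timepoint", threshold)
  )
  out
}

#' Truncate a well time series at growth saturation
#'
#' Timepoints after a culture reaches confluence are excluded because
#' growth is no longer exponential there. A timepoint is flagged as
#' saturated when its count is within `plateau_tolerance` of the running
#' maximum *and* its log-count increment has collapsed to less than 10%
#' of the median increment seen earlier in the series; the flagged point
#' and everything after it are dropped.
#'
#' @param series Data frame for one well with columns `time_hr` (strictly
#'   increasing) and `nuclei_count` (positive).
#' @param plateau_tolerance Fractional closeness to the running maximum
#'   that counts as "at plateau" (default 0.05).
#' @return The truncated series. If fewer than 2 points would remain the
#'   well is returned as a zero-row series with attribute
#'   `"excluded_reason"`.
#' @export
truncate_saturation <- function(series, plateau_tolerance = 0.05) {
  check_columns(series, c("time_hr", "nuclei_count"), "series")
  check_number(plateau_tolerance, "plateau_tolerance", min = 0)
  n <- nrow(series)
  if (n < 3L) return(series)
  if (any(series$nuclei_count <= 0)) {
    stop("`series` has non-positive counts; cannot assess saturation on the log scale",
         call. = FALSE)
  }
  if (any(diff(series$time_hr) <= 0)) {
    stop("`series` times must be strictly increasing", call. = FALSE)
  }
  counts <- series$nuclei_count
  incr <- diff(log(counts))
  run_max <- cummax(counts)
  cut <- NA_integer_
  for (k in 3:n) {
    med_earlier <- median(incr[seq_len(k - 2L)])
    at_plateau <- counts[k] >= (1 - plateau_tolerance) * run_max[k]
    stalled <- incr[k - 1L] < 0.1 * med_earlier
    if (at_plateau && stalled) {
      cut <- k
      break
    }
  }
  if (is.na(cut)) return(series)
  out <- series[seq_len(cut - 1L), , drop = FALSE]
  if (nrow(out) < 2L) {
    out <- series[0L, , drop = FALSE]
    attr(out, "excluded_reason") <- "fewer than 2 pre-saturation timepoints"
  }
  out
}

#' Fit an exponential growth rate to one well
#'
#' Models proliferation as `ln N(t) = ln N(0) + mu * t` and estimates `mu`
#' by ordinary least squares of log nuclei count on time. When `time_unit
#' = "days"` the fitted per-day slope is divided by 24 so that `mu` is
#' always reported in hr^-1.
#'
#' @param series Data frame with columns `time_hr` (or `time_day` when
#'   `time_unit = "days"`) and `nuclei_count`; all retained counts must be
#'   positive.
#' @param time_unit Unit of the time column, `"hours"` (default) or
#'   `"days"`.
#' @return An object of class `growth_fit`: list with `mu` (hr^-1),
#'   `ln_n0`, `r_squared`, `n_points_used`, `doubling_time_hr` (`NA` when
#'   `mu <= 0`).
#' @examples
#' s <- tibble::tibble(time_hr = c(0, 24, 48, 72),
#'                     nuclei_count = 100 * exp(0.03 * c(0, 24, 48, 72)))
#' fit_growth(s)$mu # 0.03
#' @export
fit_growth <- function(series, time_unit = c("hours", "days")) {
  time_unit <- match.arg(time_unit)
  time_col <- if (time_unit == "hours") "time_hr" else "time_day"
  check_columns(series, c(time_col, "nuclei_count"), "series")
  t <- series[[time_col]]
  counts <- series$nuclei_count
  if (length(t) < 2L) {
    stop("growth fit needs at least 2 timepoints", call. = FALSE)
  }
  if (any(counts <= 0)) {
    stop("retained counts must be positive: log of a non-positive count is undefined",
         call. = FALSE)
  }
  fit <- lm(log(counts) ~ t)
  slope <- unname(coef(fit)[2L])
  mu <- if (time_unit == "days") slope / 24 else slope
  ss_tot <- sum((log(counts) - mean(log(counts)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(
    list(
      mu = mu,
      ln_n0 = unname(coef(fit)[1L]),
      r_squared = r2,
      n_points_used = length(t),
      doubling_time_hr = if (mu > 0) log(2) / mu else NA_real_
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential growth fit: mu = %.4g hr^-1 (doubling %.3g h), R2 = %.3f, n = %d\n",
    x$mu, x$doubling_time_hr, x$r_squared, x$n_points_used
  ))
  invisible(x)
}

#' Doubling time from an exponential growth rate
#'
#' @param mu Growth rate constant, hr^-1; must be positive.
#' @return `ln(2) / mu`, hours.
#' @examples
#' doubling_time(0.024) # about 28.9 h
#' @export
doubling_time <- function(mu) {
  check_numeric_vector(mu, "mu")
  if (any(mu <= 0)) {
    stop("`mu` must be positive: a non-growing culture has no doubling time",
         call. = FALSE)
  }
  log(2) / mu
}

#' Fit growth rates for every well of a filtered plate
#'
#' Applies [truncate_saturation()] then [fit_growth()] per well. Wells for
#' which fewer than 2 usable points remain are dropped and recorded.
#'
#' @param plate Long-format data frame with columns `well_id`, `time_hr`,
#'   `nuclei_count` (already edge- and low-count-filtered, if desired).
#' @param plateau_tolerance Passed to [truncate_saturation()].
#' @return A tibble with one row per fitted well: `well_id`, `mu`,
#'   `ln_n0`, `r_squared`, `n_points_used`; excluded wells in attribute
#'   `"excluded"`.
#' @export
fit_plate_growth <- function(plate, plateau_tolerance = 0.05) {
  check_columns(plate, c("well_id", "time_hr", "nuclei_count"), "plate")
  wells <- split(plate, plate$well_id)
  rows <- list()
  excluded <- list()
  for (id in names(wells)) {
    s <- wells[[id]]
    s <- s[order(s$time_hr), , drop = FALSE]
    s <- truncate_saturation(s, plateau_tolerance)
    if (nrow(s) < 2L) {
      excluded[[id]] <- tibble::tibble(
        well_id = id,
        reason = attr(s, "excluded_reason") %||% "fewer than 2 timepoints"
      )
      next
    }
    f <- fit_growth(s)
    rows[[id]] <- tibble::tibble(
      well_id = id, mu = f$mu, ln_n0 = f$ln_n0,
      r_squared = f$r_squared, n_points_used = f$n_points_used
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(well_id = character(), mu = double(), ln_n0 = double(),
                   r_squared = double(), n_points_used = integer())
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    tibble::tibble(well_id = character(), reason = character())
  out
}

#' Aggregate per-well growth fits for a treatment group
#'
#' The group-level rate is the mean of replicate-level (per-well) fitted
#' rates, with a nonparametric bootstrap percentile confidence interval,
#' rather than a fit to an averaged growth curve.
#'
#' @param fits Tibble from [fit_plate_growth()] (needs column `mu`).
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed for the resampling.
#' @param level Confidence level (default 0.95).
#' @return List with `mu` (mean of well fits), `ci` (percentile bounds),
#'   `n_wells`, `n_boot`, `seed`.
#' @export
aggregate_growth <- function(fits, n_boot = 10000, seed = 1, level = 0.95) {
  check_columns(fits, "mu", "fits")
  mu <- fits$mu
  if (length(mu) == 0L) stop("no well-level fits to aggregate", call. = FALSE)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(length(mu), length(mu) * n_boot, replace = TRUE),
                  nrow = length(mu))
    colMeans(matrix(mu[idx], nrow = length(mu)))
  })
  alpha <- (1 - level) / 2
  list(
    mu = mean(mu),
    ci = unname(quantile(boots, c(alpha, 1 - alpha))),
    n_wells = length(mu),
    n_boot = n_boot,
    seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
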