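# Proteome-constrained maximal ATP production capacity -------------------

#' Bootstrap the maximal pathway-exclusive ATP production rate
#'
#' Estimates the ceiling on ATP production if the entire ATP-producing
#' proteome fraction were devoted to a single pathway:
#' `V_ATP = V_max_pathway * gamma_pathway * phi_totalATP`, where
#' `V_max_pathway` is the maximal glucose uptake rate per mg of pathway
#' protein (umol glucose mg^-1 min^-1), `gamma_pathway` the ATP yield per
#' glucose, and `phi_totalATP` the proteome fraction allocated to
#' ATP-producing enzymes. Per iteration one `v_max` and one `phi` are
#' drawn independently with replacement from their empirical
#' distributions; the product is converted to per-hour units. The point
#' estimate is the bootstrap median (the mean is available via `center`);
#' the interval is the 2.5th-97.5th percentile range.
#'
#' @param v_max_samples Empirical `V_max` samples, umol glucose
#'   (mg pathway protein)^-1 min^-1 (non-empty, >= 0).
#' @param phi_samples Empirical proteome-fraction samples in `[0, 1]`.
#' @param gamma ATP yield per glucose for the pathway (> 0).
#' @param pathway Label, `"glycolysis"` or `"respiration"`.
#' @param n_boot Iterations (default 10000).
#' @param seed Integer seed; fixed seeds give bit-identical results.
#' @param center `"median"` (default) or `"mean"` of the bootstrap
#'   distribution as the point estimate.
#' @param level Confidence level (default 0.95).
#' @return Object of class `capacity_estimate`: `point`, `ci_low`,
#'   `ci_high` (umol ATP (mg protein)^-1 hr^-1), `pathway`, `n_boot`,
#'   `seed`, and the bootstrap `draws`.
#' @export
capacity_bootstrap <- function(v_max_samples, phi_samples, gamma,
                               pathway = c("glycolysis", "respiration"),
                               n_boot = 10000, seed = 1,
                               center = c("median", "mean"), level = 0.95) {
  pathway <- match.arg(pathway)
  center <- match.arg(center)
  check_numeric_vector(v_max_samples, "v_max_samples")
  check_numeric_vector(phi_samples, "phi_samples")
  if (any(v_max_samples < 0)) {
    stop_bad_arg("v_max_samples", "must be non-negative")
  }
  if (any(phi_samples < 0 | phi_samples > 1)) {
    stop_bad_arg("phi_samples", "must lie in [0, 1]")
  }
  check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  check_number(n_boot, "n_boot", min = 1)
  draws <- with_seed(seed, {
    # index-based resampling: sample() would misread a length-1 vector
    v <- v_max_samples[sample.int(length(v_max_samples), n_boot,
                                  replace = TRUE)]
    phi <- phi_samples[sample.int(length(phi_samples), n_boot,
                                  replace = TRUE)]
    v * gamma * phi * 60 # per-minute -> per-hour
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(draws, c(alpha, 1 - alpha)))
  structure(
    list(
      point = if (center == "median") median(draws) else mean(draws),
      ci_low = ci[1L],
      ci_high = ci[2L],
      pathway = pathway,
      gamma = gamma,
      n_boot = n_boot,
      seed = seed,
      draws = draws
    ),
    class = "capacity_estimate"
  )
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat(sprintf(
    "Maximal %s ATP production capacity: %.4g [%.4g, %.4g] umol/mg/hr (n_boot = %d)\n",
    x$pathway, x$point, x$ci_low, x$ci_high, x$n_boot
  ))
  invisible(x)
}

#' Empirical cumulative distribution table
#'
#' Step-function representation `F(v) = (# values <= v) / n` of a set of
#' measured ATP production rates.
#'
#' @param values Non-empty numeric vector.
#' @return Tibble with columns `value` (sorted ascending) and `fraction`
#'   (nondecreasing, ending at 1; ties share the final fraction).
#' @export
ecdf_table <- function(values) {
  check_numeric_vector(values, "values")
  v <- sort(values)
  n <- length(v)
  # fraction at each sorted value is F evaluated there (ties collapse upward)
  frac <- vapply(v, function(x) sum(v <= x), numeric(1)) / n
  tibble::tibble(value = v, fraction = frac)
}

#' Fraction of measurements exceeding a threshold
#'
#' Used to quantify how many measured ATP production rates lie above a
#' pathway capacity line. The comparison is strict by default (values
#' exactly at the threshold do not count as above).
#'
#' @param values Non-empty numeric vector.
#' @param threshold Capacity or other cut-off, same units.
#' @param strict Use `>` (default) rather than `>=`.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_exceeding <- function(values, threshold, strict = TRUE) {
  check_numeric_vector(values, "values")
  check_number(threshold, "threshold")
  if (strict) mean(values > threshold) else mean(values >= threshold)
}

#' Maximal growth rate a pathway capacity can support
#'
#' Inverts the fitted ATP-growth line at the capacity estimate:
#' `mu_max = (capacity - intercept) / slope`, with the capacity CI
#' endpoints propagated through the same transform. A capacity below the
#' maintenance intercept yields `mu_max = 0` with a warning.
#'
#' @param fit A [line_fit][fit_line] with positive slope.
#' @param capacity A [capacity_estimate][capacity_bootstrap].
#' @return List with `mu_max` (hr^-1), `ci` (from the capacity CI), and
#'   `doubling_time_hr` (`NA` when `mu_max = 0`).
#' @export
max_growth_supported <- function(fit, capacity) {
  stopifnot(inherits(fit, "line_fit"), inherits(capacity, "capacity_estimate"))
  if (fit$slope <= 0) {
    stop("ATP-growth slope must be positive to invert the line", call. = FALSE)
  }
  invert <- function(cap) max((cap - fit$intercept) / fit$slope, 0)
  mu_max <- invert(capacity$point)
  if (capacity$point < fit$intercept) {
    warning("capacity below the maintenance intercept; mu_max reported as 0",
            call. = FALSE)
  }
  list(
    mu_max = mu_max,
    ci = c(invert(capacity$ci_low), invert(capacity$ci_high)),
    doubling_time_hr = if (mu_max > 0) log(2) / mu_max else NA_real_
  )
}

#' Shortest doubling time a pathway can sustain
#'
#' `ln(2) / mu_max` for the maximal pathway-supported growth rate; e.g.
#' a respiration-supported ceiling of 0.024 hr^-1 corresponds to a
#' doubling time of about 28.9 h.
#'
#' @param mu_max Maximal supportable growth rate, hr^-1 (> 0).
#' @return Hours.
#' @export
respiration_limit_doubling_time <- function(mu_max) {
  check_number(mu_max, "mu_max")
  if (mu_max <= 0) {
    stop("`mu_max` must be positive; no finite doubling time exists",
         call. = FALSE)
  }
  log(2) / mu_max
}
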