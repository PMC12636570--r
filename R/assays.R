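# Raw assay normalization: lactate, Seahorse OCR, BCA protein ------------

#' Per-cell-line size and protein descriptor
#'
#' Conversion constants used to normalize per-cell measurements to
#' per-mg-protein rates: mean cell volume (Coulter counter) and protein
#' mass per unit volume (BCA), whose product is the protein mass per cell.
#'
#' @param cell_line Label.
#' @param mean_volume_fl Mean cell volume, fL.
#' @param protein_per_volume_mg_per_fl Protein density, mg / fL.
#' @param volume_sd_fl Volume standard deviation, fL (optional, recorded).
#' @return Object of class `cell_descriptor` with the above fields plus
#'   `protein_per_cell_mg`.
#' @export
cell_descriptor <- function(cell_line, mean_volume_fl,
                            protein_per_volume_mg_per_fl,
                            volume_sd_fl = NA_real_) {
  check_number(mean_volume_fl, "mean_volume_fl", min = 0, strict_min = TRUE)
  check_number(protein_per_volume_mg_per_fl, "protein_per_volume_mg_per_fl",
               min = 0, strict_min = TRUE)
  structure(
    list(
      cell_line = cell_line,
      mean_volume_fl = mean_volume_fl,
      volume_sd_fl = volume_sd_fl,
      protein_per_volume_mg_per_fl = protein_per_volume_mg_per_fl,
      protein_per_cell_mg = mean_volume_fl * protein_per_volume_mg_per_fl
    ),
    class = "cell_descriptor"
  )
}

#' Fit a linear standard curve
#'
#' Least-squares line mapping standard concentration to the measured
#' kinetic signal (e.g. the OD490 slope of each lactate standard). The
#' returned object supports inverse prediction of unknowns via
#' [invert_standard_curve()].
#'
#' @param concentrations Standard concentrations (>= 3 distinct values).
#' @param signals Measured signal per standard, same length.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `n`, `range` (of the standards' concentrations).
#' @export
fit_standard_curve <- function(concentrations, signals) {
  check_numeric_vector(concentrations, "concentrations", min_len = 3L)
  check_numeric_vector(signals, "signals", min_len = 3L)
  if (length(concentrations) != length(signals)) {
    stop("`concentrations` and `signals` must have equal length", call. = FALSE)
  }
  if (var(concentrations) == 0) {
    stop("standards are degenerate: all concentrations identical", call. = FALSE)
  }
  fit <- lm(signals ~ concentrations)
  ss_tot <- sum((signals - mean(signals))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(
    list(
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = r2,
      n = length(signals),
      range = range(concentrations)
    ),
    class = "standard_curve"
  )
}

#' Invert a standard curve to estimate concentration from signal
#'
#' @param curve A [standard_curve][fit_standard_curve].
#' @param signal Measured signal value(s).
#' @param warn_extrapolation Warn when the implied concentration falls
#'   outside the standards' range (default `TRUE`).
#' @return Estimated concentration(s), `(signal - intercept) / slope`.
#' @export
invert_standard_curve <- function(curve, signal, warn_extrapolation = TRUE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) {
    stop("standard curve has zero slope; inverse prediction is undefined",
         call. = FALSE)
  }
  conc <- (signal - curve$intercept) / curve$slope
  if (warn_extrapolation &&
      any(conc < curve$range[1L] | conc > curve$range[2L])) {
    warning("inverse prediction extrapolates beyond the standard range",
            call. = FALSE)
  }
  conc
}

#' Lactate production rate from a timed media sampling course
#'
#' The total lactate amount in the medium (concentration x volume) is
#' regressed on sampling time; the slope, divided by the total protein
#' mass of the cells in the well, is the lactate production rate.
#'
#' @param times_hr Sampling times, hours (>= 2, spanning > 0 h).
#' @param conc_umol_per_ml Medium lactate concentration at each sampling
#'   time, umol/mL (= mM).
#' @param medium_volume_ml Medium volume, mL.
#' @param cell_count Number of cells in the well at assay end.
#' @param descriptor A [cell_descriptor()] for the line.
#' @return Rate in umol (mg protein)^-1 hr^-1.
#' @export
lactate_production_rate <- function(times_hr, conc_umol_per_ml,
                                    medium_volume_ml, cell_count, descriptor) {
  check_numeric_vector(times_hr, "times_hr", min_len = 2L)
  check_numeric_vector(conc_umol_per_ml, "conc_umol_per_ml", min_len = 2L)
  if (length(times_hr) != length(conc_umol_per_ml)) {
    stop("`times_hr` and `conc_umol_per_ml` must have equal length",
         call. = FALSE)
  }
  if (diff(range(times_hr)) <= 0) {
    stop("sampling times must span a positive interval", call. = FALSE)
  }
  check_number(medium_volume_ml, "medium_volume_ml", min = 0, strict_min = TRUE)
  check_number(cell_count, "cell_count", min = 0, strict_min = TRUE)
  stopifnot(inherits(descriptor, "cell_descriptor"))
  protein_mg <- cell_count * descriptor$protein_per_cell_mg
  if (protein_mg <= 0) {
    stop("total protein mass must be positive", call. = FALSE)
  }
  amount_umol <- conc_umol_per_ml * medium_volume_ml
  slope <- unname(coef(lm(amount_umol ~ times_hr))[2L])
  slope / protein_mg
}

#' Summarize a Seahorse-style OCR trace
#'
#' Raw oxygen consumption values are clamped at zero (negative
#' instrument readings are reported as zero), then averaged within each
#' injection phase (3 measurements per phase). The basal-phase mean is
#' normalized by the well's protein mass and converted from per-minute to
#' per-hour units.
#'
#' @param trace Data frame with columns `phase` (one of `basal`,
#'   `oligomycin`, `fccp1`, `fccp2`, `antimycin_rotenone`),
#'   `measurement_index`, `value`.
#' @param cell_count Cells in the well at assay end.
#' @param descriptor A [cell_descriptor()].
#' @param value_unit Unit of `value`: `"umol_per_min"` (default) or
#'   `"pmol_per_min"` (Seahorse native; converted by 1e-6).
#' @return List with `basal_ocr` (umol O2 (mg protein)^-1 hr^-1),
#'   `phase_means` (clamped per-phase means in the input's per-minute
#'   unit), and `protein_mg`.
#' @export
process_seahorse <- function(trace, cell_count, descriptor,
                             value_unit = c("umol_per_min", "pmol_per_min")) {
  value_unit <- match.arg(value_unit)
  check_columns(trace, c("phase", "value"), "trace")
  check_number(cell_count, "cell_count", min = 0, strict_min = TRUE)
  stopifnot(inherits(descriptor, "cell_descriptor"))
  known <- c("basal", "oligomycin", "fccp1", "fccp2", "antimycin_rotenone")
  if (!all(trace$phase %in% known)) {
    stop("trace contains unknown phase labels", call. = FALSE)
  }
  if (!"basal" %in% trace$phase) {
    stop("trace has no basal phase; basal OCR cannot be computed",
         call. = FALSE)
  }
  counts <- table(trace$phase)
  if (any(counts != 3L)) {
    warning("expected exactly 3 measurements per phase", call. = FALSE)
  }
  clamped <- pmax(trace$value, 0)
  phase_means <- vapply(split(clamped, trace$phase), mean, numeric(1))
  protein_mg <- cell_count * descriptor$protein_per_cell_mg
  scale <- if (value_unit == "pmol_per_min") 1e-6 else 1
  basal <- unname(phase_means[["basal"]]) * scale / protein_mg * 60
  list(
    basal_ocr = basal,
    phase_means = phase_means,
    protein_mg = protein_mg
  )
}

#' Protein content per cell and per volume from a BCA assay
#'
#' Fits a BSA standard curve (OD vs concentration), inverse-predicts the
#' sample lysate concentration, and converts to protein per cell and per
#' unit cell volume.
#'
#' @param standard_concs BSA standard concentrations, mg/mL (>= 3).
#' @param standard_ods Standard absorbances (e.g. A562).
#' @param sample_ods Sample absorbance(s); replicates are averaged.
#' @param cells_assayed Number of cells lysed.
#' @param mean_volume_fl Mean cell volume, fL.
#' @param lysate_volume_ml Lysate volume, mL (default 0.5).
#' @return List with `sample_conc_mg_per_ml`, `protein_per_cell_mg`,
#'   `protein_per_volume_mg_per_fl`, and the fitted `curve`.
#' @export
bca_protein <- function(standard_concs, standard_ods, sample_ods,
                        cells_assayed, mean_volume_fl,
                        lysate_volume_ml = 0.5) {
  curve <- fit_standard_curve(standard_concs, standard_ods)
  check_number(cells_assayed, "cells_assayed", min = 0, strict_min = TRUE)
  check_number(mean_volume_fl, "mean_volume_fl", min = 0, strict_min = TRUE)
  check_number(lysate_volume_ml, "lysate_volume_ml", min = 0, strict_min = TRUE)
  conc <- invert_standard_curve(curve, mean(sample_ods))
  protein_mg <- conc * lysate_volume_ml
  protein_per_cell <- protein_mg / cells_assayed
  list(
    sample_conc_mg_per_ml = conc,
    protein_per_cell_mg = protein_per_cell,
    protein_per_volume_mg_per_fl = protein_per_cell / mean_volume_fl,
    curve = curve
  )
}
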