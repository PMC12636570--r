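# End-to-end analysis pipeline -------------------------------------------

#' Run the full ATP-growth accounting analysis
#'
#' Composes the pipeline stages on a flux-growth table: yield
#' stoichiometry, ATP-growth regression with bootstrap confidence
#' intervals, the 95% prediction band, optional pathway-capacity
#' estimates (with the maximal growth rate each capacity supports and
#' the fraction of measurements exceeding it), and the theoretical
#' biomass ATP demand compared against the fitted slope.
#'
#' @param flux_table A flux-growth tibble (see [read_flux_table()]) or a
#'   path to one.
#' @param organism `"ecoli"`, `"yeast"` or `"mammalian"`; defaults to the
#'   value in the table's `organism` column.
#' @param n_boot Bootstrap iterations for the regression and capacities.
#' @param seed Integer seed recorded in every output.
#' @param level Prediction-band / CI level.
#' @param capacity_inputs Optional named list of capacity inputs, each a
#'   list with `v_max_samples`, `phi_samples`, `gamma` and `pathway`
#'   (passed to [capacity_bootstrap()]).
#' @param biomass_composition Optional composition (see
#'   [default_biomass_composition()]); defaults to the organism's
#'   reconstruction.
#' @param out_dir Optional directory; when given, writes
#'   `line_fit.json`, `band.csv` and `results.json` there.
#' @return List with elements `points` (growth, fluxes and ATP
#'   components), `fit`, `band`, `capacities`, `biomass` and `seed`.
#' @export
run_pipeline <- function(flux_table, organism = NULL, n_boot = 10000,
                         seed = 1, level = 0.95, capacity_inputs = NULL,
                         biomass_composition = NULL, out_dir = NULL) {
  check_number(n_boot, "n_boot", min = 1)
  if (is.character(flux_table)) flux_table <- read_flux_table(flux_table)
  check_columns(flux_table,
                c("growth_rate_per_hr", "lactate", "ethanol", "acetate", "o2"),
                "flux_table")
  if (is.null(organism)) {
    organism <- unique(flux_table$organism)
    if (length(organism) != 1L) {
      stop("flux table mixes organisms; pass `organism` explicitly",
           call. = FALSE)
    }
  }
  model <- preset_yield_model(organism)

  atp <- atp_from_fluxes(
    lactate_rate = flux_table$lactate, o2_rate = flux_table$o2,
    ethanol_rate = flux_table$ethanol, acetate_rate = flux_table$acetate,
    model = model
  )
  points <- tibble::tibble(
    condition = flux_table$condition,
    growth_rate = flux_table$growth_rate_per_hr,
    atp_glycolytic = atp$glycolytic,
    atp_respiratory = atp$respiratory,
    atp_total = atp$total
  )

  fit <- bootstrap_fit(points, n_iter = n_boot, seed = seed, level = level)
  band_x <- seq(min(points$growth_rate), max(points$growth_rate),
                length.out = 100)
  band <- prediction_band(fit, band_x, level = level)

  capacities <- NULL
  if (!is.null(capacity_inputs)) {
    capacities <- lapply(capacity_inputs, function(ci) {
      est <- capacity_bootstrap(
        v_max_samples = ci$v_max_samples, phi_samples = ci$phi_samples,
        gamma = ci$gamma, pathway = ci$pathway, n_boot = n_boot, seed = seed,
        level = level
      )
      list(
        estimate = est,
        max_growth = max_growth_supported(fit, est),
        fraction_above = fraction_exceeding(points$atp_total, est$point)
      )
    })
  }

  if (is.null(biomass_composition)) {
    biomass_composition <- default_biomass_composition(organism)
  }
  demand_protein <- biomass_atp_demand(biomass_composition,
                                       basis = "per_mg_protein")
  biomass <- list(
    demand_per_mg_dry_mass = biomass_atp_demand(biomass_composition),
    demand_per_mg_protein = demand_protein,
    theoretical_fraction = theoretical_fraction(demand_protein, fit$slope)
  )

  result <- list(points = points, fit = fit, band = band,
                 capacities = capacities, biomass = biomass,
                 organism = organism, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_line_fit_json(fit, file.path(out_dir, "line_fit.json"))
    write_band_csv(band, file.path(out_dir, "band.csv"))
    summary_payload <- list(
      organism = organism, seed = seed, n_boot = n_boot,
      slope = fit$slope, intercept = fit$intercept,
      slope_ci = fit$slope_ci, intercept_ci = fit$intercept_ci,
      r_squared = fit$r_squared, p_value = fit$p_value,
      biomass = biomass[c("demand_per_mg_dry_mass", "demand_per_mg_protein")],
      theoretical_fraction = as.numeric(biomass$theoretical_fraction),
      capacities = lapply(capacities, function(cp) list(
        pathway = cp$estimate$pathway, point = cp$estimate$point,
        ci = c(cp$estimate$ci_low, cp$estimate$ci_high),
        mu_max = cp$max_growth$mu_max,
        doubling_time_hr = cp$max_growth$doubling_time_hr,
        fraction_above = cp$fraction_above
      ))
    )
    jsonlite::write_json(summary_payload,
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}
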