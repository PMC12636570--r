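# ATP yield stoichiometry ------------------------------------------------

#' Organism-specific ATP yield model
#'
#' Constructs the set of stoichiometric constants used to convert measured
#' byproduct-production and oxygen-consumption rates into ATP production
#' rates. Fermentative glycolysis yields 2 ATP per glucose in all three
#' organisms; effective respiratory yields per fully oxidized glucose are
#' 20 ATP for *E. coli*, 16 ATP for *S. cerevisiae* and 24 ATP for
#' mammalian cells, with 6 mol O2 consumed per mol glucose. The *E. coli*
#' model additionally carries the Pta-AckA acetate-overflow pathway yield
#' of 10 ATP per glucose (which includes electron-transport oxidation of
#' the 4 NADH the pathway generates).
#'
#' @param organism One of `"ecoli"`, `"yeast"`, `"mammalian"`.
#' @param acetate_substrate_level_atp_per_acetate ATP credited per excreted
#'   acetate when combining acetate flux with a separately measured O2
#'   flux. The default 2 counts only substrate-level phosphorylation
#'   (glycolytic 2 ATP + AckA 2 ATP per glucose, i.e. 2 per acetate), so
#'   that NADH-derived ATP is not double-counted against the O2 term. Set
#'   to 5 (10 ATP per glucose over 2 acetate) to use the full pathway
#'   yield for datasets without O2 measurements.
#' @return An object of class `atp_yield_model`: a list with fields
#'   `organism`, `fermentation_atp_per_glucose`,
#'   `respiration_atp_per_glucose`, `o2_per_glucose`,
#'   `acetate_pathway_atp_per_glucose` (`NA` except for *E. coli*),
#'   `acetate_substrate_level_atp_per_acetate` and `nadph_atp_equiv`.
#' @examples
#' preset_yield_model("mammalian")$respiration_atp_per_glucose # 24
#' preset_yield_model("ecoli")$acetate_pathway_atp_per_glucose # 10
#' @export
preset_yield_model <- function(organism = c("ecoli", "yeast", "mammalian"),
                               acetate_substrate_level_atp_per_acetate = 2) {
  organism <- match.arg(organism)
  check_number(acetate_substrate_level_atp_per_acetate,
               "acetate_substrate_level_atp_per_acetate", min = 0)
  respiration <- switch(organism, ecoli = 20, yeast = 16, mammalian = 24)
  model <- list(
    organism = organism,
    fermentation_atp_per_glucose = 2,
    respiration_atp_per_glucose = respiration,
    o2_per_glucose = 6,
    acetate_pathway_atp_per_glucose = if (organism == "ecoli") 10 else NA_real_,
    acetate_substrate_level_atp_per_acetate =
      acetate_substrate_level_atp_per_acetate,
    nadph_atp_equiv = 2.5
  )
  structure(model, class = "atp_yield_model")
}

#' @export
print.atp_yield_model <- function(x, ...) {
  cat("ATP yield model (", x$organism, ")\n", sep = "")
  cat("  fermentation: ", x$fermentation_atp_per_glucose,
      " ATP / glucose\n", sep = "")
  cat("  respiration:  ", x$respiration_atp_per_glucose,
      " ATP / glucose (", x$o2_per_glucose, " O2 / glucose)\n", sep = "")
  if (!is.na(x$acetate_pathway_atp_per_glucose)) {
    cat("  acetate pathway: ", x$acetate_pathway_atp_per_glucose,
        " ATP / glucose\n", sep = "")
  }
  invisible(x)
}

#' ATP produced per mole of oxygen consumed
#'
#' Bridges the per-glucose respiratory yield to per-O2 measurements:
#' `respiration_atp_per_glucose / o2_per_glucose` (e.g. 24/6 = 4 for
#' mammalian cells).
#'
#' @param model An [atp_yield_model][preset_yield_model].
#' @return Dimensionless ratio, mol ATP per mol O2.
#' @export
atp_per_o2 <- function(model) {
  stopifnot(inherits(model, "atp_yield_model"))
  if (!is.numeric(model$o2_per_glucose) || model$o2_per_glucose <= 0) {
    stop("yield model has non-positive `o2_per_glucose`", call. = FALSE)
  }
  model$respiration_atp_per_glucose / model$o2_per_glucose
}

#' Convert measured fluxes to ATP production rates
#'
#' Applies the yield stoichiometry to measured byproduct production and
#' oxygen consumption rates. One lactate (or ethanol) carries 1 ATP of
#' substrate-level phosphorylation (2 ATP per glucose, 2 product molecules
#' per glucose); acetate carries
#' `model$acetate_substrate_level_atp_per_acetate`; the respiratory rate is
#' the O2 consumption rate times [atp_per_o2()].
#'
#' All rates are in canonical units of umol (mg protein)^-1 hr^-1.
#' Arguments are vectorized over observations.
#'
#' @param lactate_rate,o2_rate,ethanol_rate,acetate_rate Non-negative
#'   fluxes, umol (mg protein)^-1 hr^-1.
#' @param model An [atp_yield_model][preset_yield_model].
#' @return A tibble of class `atp_production_rate` with columns
#'   `glycolytic`, `respiratory` and `total` (their sum), same units.
#' @examples
#' m <- preset_yield_model("mammalian")
#' atp_from_fluxes(lactate_rate = 3, o2_rate = 1.5, model = m)$total # 9
#' @export
atp_from_fluxes <- function(lactate_rate = 0, o2_rate = 0, ethanol_rate = 0,
                            acetate_rate = 0, model) {
  stopifnot(inherits(model, "atp_yield_model"))
  n <- max(length(lactate_rate), length(o2_rate), length(ethanol_rate),
           length(acetate_rate))
  lactate_rate <- rep_len(lactate_rate, n)
  o2_rate <- rep_len(o2_rate, n)
  ethanol_rate <- rep_len(ethanol_rate, n)
  acetate_rate <- rep_len(acetate_rate, n)
  for (field in c("lactate_rate", "o2_rate", "ethanol_rate", "acetate_rate")) {
    v <- get(field)
    if (!is.numeric(v) || anyNA(v)) {
      stop_bad_arg(field, "must be numeric with no missing values")
    }
    if (any(v < 0)) {
      stop_bad_arg(field, "contains a negative rate; fluxes must be >= 0")
    }
  }
  k_acetate <- model$acetate_substrate_level_atp_per_acetate
  glycolytic <- lactate_rate + ethanol_rate + k_acetate * acetate_rate
  respiratory <- atp_per_o2(model) * o2_rate
  out <- tibble::tibble(
    glycolytic = glycolytic,
    respiratory = respiratory,
    total = glycolytic + respiratory
  )
  class(out) <- c("atp_production_rate", class(out))
  out
}
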