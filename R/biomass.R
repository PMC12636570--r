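# Theoretical ATP demand of biomass synthesis ----------------------------

#' ATP-equivalent cost of synthesizing one C16 fatty acid
#'
#' Sums the ATP spent on acetyl-CoA carboxylation with the NADPH required
#' for chain elongation, converted at the stated ATP-equivalence ratio:
#' `atp_carboxylation + nadph_count * nadph_atp_equiv`. With the default
#' palmitate stoichiometry (7 ATP, 14 NADPH, 2.5 ATP per NADPH) the cost
#' is 42 ATP equivalents per molecule.
#'
#' @param atp_carboxylation ATP for acetyl-CoA carboxylation per C16
#'   chain (default 7).
#' @param nadph_count NADPH per C16 chain (default 14).
#' @param nadph_atp_equiv ATP equivalents per NADPH (default 2.5).
#' @return ATP equivalents per fatty acid molecule.
#' @examples
#' fatty_acid_cost() # 42
#' @export
fatty_acid_cost <- function(atp_carboxylation = 7, nadph_count = 14,
                            nadph_atp_equiv = 2.5) {
  check_number(atp_carboxylation, "atp_carboxylation", min = 0)
  check_number(nadph_count, "nadph_count", min = 0)
  check_number(nadph_atp_equiv, "nadph_atp_equiv", min = 0)
  atp_carboxylation + nadph_count * nadph_atp_equiv
}

#' Average ATP cost per nucleotide
#'
#' Weighted mean of the de novo purine and pyrimidine synthesis costs.
#' With 12 ATP per purine, 8 ATP per pyrimidine and a 1:1 ratio the
#' average is 10 ATP per nucleotide.
#'
#' @param purine_atp ATP per purine nucleotide (default 12).
#' @param pyrimidine_atp ATP per pyrimidine nucleotide (default 8).
#' @param purine_fraction Purine fraction in `[0, 1]` (default 0.5).
#' @return ATP per nucleotide.
#' @examples
#' average_nucleotide_cost() # 10
#' @export
average_nucleotide_cost <- function(purine_atp = 12, pyrimidine_atp = 8,
                                    purine_fraction = 0.5) {
  check_number(purine_atp, "purine_atp", min = 0)
  check_number(pyrimidine_atp, "pyrimidine_atp", min = 0)
  check_number(purine_fraction, "purine_fraction", min = 0)
  if (purine_fraction > 1) {
    stop_bad_arg("purine_fraction", "must lie in [0, 1]")
  }
  purine_fraction * purine_atp + (1 - purine_fraction) * pyrimidine_atp
}

#' Macromolecule synthesis cost specification
#'
#' @param name One of `"protein"`, `"lipid"`, `"rna"`, `"dna"`.
#' @param atp_per_monomer ATP equivalents to incorporate one monomer.
#' @param monomer_mass_da Monomer mass, Da.
#' @return Object of class `macromolecule_spec`.
#' @export
macromolecule_spec <- function(name = c("protein", "lipid", "rna", "dna"),
                               atp_per_monomer, monomer_mass_da) {
  name <- match.arg(name)
  check_number(atp_per_monomer, "atp_per_monomer", min = 0, strict_min = TRUE)
  check_number(monomer_mass_da, "monomer_mass_da", min = 0, strict_min = TRUE)
  structure(
    list(name = name, atp_per_monomer = atp_per_monomer,
         monomer_mass_da = monomer_mass_da),
    class = "macromolecule_spec"
  )
}

#' Default per-monomer synthesis costs
#'
#' Protein: ~4 ATP equivalents per amino acid (tRNA charging, ribosomal
#' elongation GTP, initiation/termination overhead) at 110 Da per
#' residue. Lipid: all lipid taken as palmitate, [fatty_acid_cost()] = 42
#' ATP at 256 Da. RNA and DNA share the [average_nucleotide_cost()] = 10
#' ATP at 330 Da per nucleotide.
#'
#' @return Named list of [macromolecule_spec()] objects for `protein`,
#'   `lipid`, `rna`, `dna`.
#' @export
default_macromolecule_specs <- function() {
  list(
    protein = macromolecule_spec("protein", 4, 110),
    lipid = macromolecule_spec("lipid", fatty_acid_cost(), 256),
    rna = macromolecule_spec("rna", average_nucleotide_cost(), 330),
    dna = macromolecule_spec("dna", average_nucleotide_cost(), 330)
  )
}

#' ATP cost per mg of a macromolecule class
#'
#' One mg of a polymer of monomer mass `m` Da contains `1/m` mmol =
#' `1000/m` umol of monomers, so the cost is
#' `atp_per_monomer / monomer_mass_da * 1000` umol ATP per mg.
#'
#' @param spec A [macromolecule_spec()].
#' @return umol ATP per mg macromolecule.
#' @examples
#' unit_cost_per_mg(macromolecule_spec("protein", 4, 110)) # 36.36
#' @export
unit_cost_per_mg <- function(spec) {
  stopifnot(inherits(spec, "macromolecule_spec"))
  if (spec$monomer_mass_da <= 0) {
    stop("monomer mass must be positive", call. = FALSE)
  }
  spec$atp_per_monomer / spec$monomer_mass_da * 1000
}

#' Reconstructed biomass compositions by organism
#'
#' Dry-mass macromolecule fractions assembled from standard literature
#' composition tables. These are documented reconstructions of typical
#' compositions (the canonical *E. coli* budget, lab-strain yeast, and
#' cultured mammalian cells), intended as configurable defaults rather
#' than measured values; override them with your own table whenever one
#' is available.
#'
#' @param organism `"ecoli"`, `"yeast"` or `"mammalian"`.
#' @return List with `organism`, `mass_fractions` (named: `protein`,
#'   `lipid`, `rna`, `dna`; fractions of dry mass summing to <= 1) and
#'   `protein_fraction` (for the per-mg-protein basis).
#' @export
default_biomass_composition <- function(organism = c("ecoli", "yeast",
                                                     "mammalian")) {
  organism <- match.arg(organism)
  fr <- switch(organism,
    ecoli = c(protein = 0.55, lipid = 0.09, rna = 0.20, dna = 0.03),
    yeast = c(protein = 0.45, lipid = 0.07, rna = 0.11, dna = 0.01),
    mammalian = c(protein = 0.60, lipid = 0.15, rna = 0.05, dna = 0.02)
  )
  list(organism = organism, mass_fractions = fr,
       protein_fraction = unname(fr[["protein"]]))
}

#' Theoretical ATP demand of biomass synthesis
#'
#' Weighted sum of per-mg synthesis costs over macromolecule classes:
#' `demand = sum_i mass_fraction_i * unit_cost_per_mg(spec_i)`. On the
#' `per_mg_protein` basis the dry-mass demand is divided by the protein
#' fraction, putting it in the units of the empirical ATP-growth slope
#' (umol ATP per mg protein).
#'
#' @param composition As returned by [default_biomass_composition()] (or
#'   a compatible list).
#' @param specs Named list of [macromolecule_spec()] objects covering
#'   every component of `composition` (default
#'   [default_macromolecule_specs()]).
#' @param basis `"per_mg_dry_mass"` (default) or `"per_mg_protein"`.
#' @return umol ATP per mg (dry mass or protein).
#' @export
biomass_atp_demand <- function(composition,
                               specs = default_macromolecule_specs(),
                               basis = c("per_mg_dry_mass", "per_mg_protein")) {
  basis <- match.arg(basis)
  fr <- composition$mass_fractions
  if (is.null(fr) || !is.numeric(fr) || is.null(names(fr))) {
    stop("`composition$mass_fractions` must be a named numeric vector",
         call. = FALSE)
  }
  if (any(fr < 0 | fr > 1) || sum(fr) > 1 + 1e-9) {
    stop("mass fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  missing <- setdiff(names(fr), names(specs))
  if (length(missing) > 0L) {
    stop(sprintf("no macromolecule spec for component(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  costs <- vapply(names(fr), function(nm) unit_cost_per_mg(specs[[nm]]),
                  numeric(1))
  demand <- sum(fr * costs)
  if (basis == "per_mg_protein") {
    pf <- composition$protein_fraction
    if (is.null(pf) || pf <= 0) {
      stop("`composition$protein_fraction` must be positive for the per-mg-protein basis",
           call. = FALSE)
    }
    demand <- demand / pf
  }
  demand
}

#' Theoretical fraction of the empirical ATP cost of growth
#'
#' Ratio of the theoretical biosynthetic ATP demand to the empirical
#' ATP-growth slope, both in umol ATP per mg. Values above 1 are reported
#' uncapped with attribute `exceeds_empirical = TRUE`.
#'
#' @param demand Theoretical demand, umol ATP per mg.
#' @param empirical_slope Fitted ATP-growth slope, same units (> 0).
#' @return The fraction `demand / empirical_slope`.
#' @export
theoretical_fraction <- function(demand, empirical_slope) {
  check_number(demand, "demand", min = 0)
  check_number(empirical_slope, "empirical_slope", min = 0)
  if (empirical_slope <= 0) {
    stop_bad_arg("empirical_slope", "must be positive")
  }
  out <- demand / empirical_slope
  if (out > 1) attr(out, "exceeds_empirical") <- TRUE
  out
}
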