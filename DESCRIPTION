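Package: atpgrowth
Title: Bioenergetic Growth Accounting from Flux and Proliferation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the coupling between cellular ATP
    production and growth rate. Converts lactate production, ethanol and
    acetate excretion, and oxygen consumption into glycolytic and
    respiratory ATP production rates using organism-specific yield
    stoichiometry; fits exponential growth rates from microplate nuclei
    counts with edge-well, low-count and saturation filters; normalizes
    colorimetric lactate and extracellular-flux (Seahorse-style) assays to
    per-mg-protein rates; fits the linear ATP-growth relationship with
    bootstrap confidence intervals and classical prediction bands;
    estimates proteome-constrained maximal pathway ATP production
    capacities and the growth rates they can support; and computes the
    theoretical ATP demand of biomass synthesis from macromolecule mass
    fractions and per-monomer costs. A synthetic-data generator with known
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
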