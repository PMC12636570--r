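---
title: "ATP-growth accounting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ATP-growth accounting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpgrowth)
```

## The model

Proliferating cells fund biomass synthesis and maintenance from two ATP
sources: fermentative glycolysis (tracked through excreted lactate,
ethanol or acetate) and respiration (tracked through oxygen
consumption). The package's central objects are:

1. **A linear ATP-growth law.** Total ATP production rate
   $J_{ATP} = s\,\mu + m$, with slope $s$ (umol ATP per mg protein — the
   energetic cost of one mg of protein-equivalent biomass) and intercept
   $m$ (the maintenance rate, umol ATP mg$^{-1}$ hr$^{-1}$). $s$ and $m$
   come from ordinary least squares; uncertainty from a nonparametric
   case-resampling bootstrap.
2. **Yield stoichiometry.** Fermentation yields 2 ATP per glucose in all
   three organisms, hence 1 ATP per excreted lactate or ethanol
   (2 product molecules per glucose). Effective respiratory yields per
   fully oxidized glucose are 20 (*E. coli*), 16 (*S. cerevisiae*) and
   24 (mammalian), with 6 O$_2$ per glucose, so measured O$_2$
   consumption converts at $\gamma_{resp}/6$ ATP per O$_2$. These
   effective yields fold in electron-transport proton stoichiometry and
   proton leak; the package treats them as constants, not quantities it
   derives.
3. **Proteome-constrained capacity.** If the whole ATP-producing
   proteome fraction $\phi$ were allocated to one pathway, the ceiling is
   $V_{ATP} = V_{max} \cdot \gamma \cdot \phi$, bootstrapped over the
   empirical distributions of $V_{max}$ and $\phi$.
4. **Biosynthetic demand.** The theoretical ATP cost of biomass is
   $\sum_i f_i \cdot c_i$ over macromolecule classes, with $f_i$ a dry
   mass fraction and $c_i$ the per-mg synthesis cost derived from
   per-monomer costs: 4 ATP per 110 Da amino acid, 42 ATP per 256 Da
   palmitate (7 ATP carboxylation + 14 NADPH at 2.5 ATP each), and 10
   ATP per 330 Da nucleotide (12 per purine, 8 per pyrimidine, 1:1).

## Assumptions

- Glucose is the sole catabolic substrate; all fermentative ATP is
  visible in excreted byproducts and all respiratory ATP in O$_2$
  consumption.
- Growth is exponential between seeding and confluence, so
  $\ln N_t = \ln N_0 + \mu t$ holds on the retained timepoints.
- The ATP-growth relationship is linear with homoscedastic scatter for
  the purposes of the prediction band (the band uses the classical
  normal-theory interval); real flux data tend to have scatter that
  grows with the mean, which the bootstrap CI accommodates but the band
  only approximates.
- GTP and ATP are interchangeable "ATP equivalents", and NADPH converts
  at a fixed 2.5 ATP equivalents.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `acetate_substrate_level_atp_per_acetate` | 2 | ATP/acetate | see below |
| low-count threshold | 100 | nuclei | seeding/segmentation failures |
| `plateau_tolerance` | 0.05 | fraction | closeness to running max that counts as confluent |
| `n_iter` / `n_boot` | 10,000 | iterations | percentile CIs stable to ~0.1% |
| band `level` | 0.95 | fraction | future-observation coverage |
| `nadph_atp_equiv` | 2.5 | ATP/NADPH | standard equivalence |
| `purine_fraction` | 0.5 | fraction | 1:1 purine:pyrimidine |

**Acetate without double counting.** The *E. coli* acetate-overflow
pathway yields about 10 ATP per glucose, but 8 of those come from
electron-transport oxidation of the pathway's 4 NADH — ATP that is
*also* counted when measured O$_2$ consumption is converted through the
respiratory yield. When both acetate and O$_2$ fluxes are available, the
package therefore credits acetate only its substrate-level share
(2 ATP per acetate: glycolytic 2 + acetate-kinase 2 per glucose, halved
per acetate molecule). For datasets lacking O$_2$ measurements the full
5 ATP per acetate (10 per glucose) is selectable via
`preset_yield_model(acetate_substrate_level_atp_per_acetate = 5)`. This
is a documented modeling choice: published totals do not state how the
two measurements were combined, and exposing both options lets users
match either convention.

## Growth-curve filters and numerical choices

- **Edge wells** (first/last row/column) are removed before fitting;
  evaporation depresses their growth. The synthetic plates build in a
  20% edge growth deficit so the filter's effect is testable.
- **Low counts**: a well is excluded if any timepoint falls below 100
  nuclei; exactly 100 passes (the rule is strict `<`).
- **Saturation**: there is no universally accepted definition of "the
  culture saturated", so the package uses an explicit, configurable
  rule: timepoint $t_k$ is saturated when its count is within
  `plateau_tolerance` (default 5%) of the running maximum *and* its
  log-increment is below 10% of the median earlier increment; $t_k$ and
  later points are dropped. A steeply *decreasing* series is not
  "saturated" under this rule — it is kept, and the fit reports a
  negative rate, which is the honest description of a dying well.
- **Fitting** is plain OLS of $\ln$(count) on time; per-day slopes are
  converted by dividing by 24. Zero counts among retained points are an
  error (the log is undefined), but zeros at filtered-out timepoints
  never poison a fit. Replicate handling is fit-per-well, then
  aggregate: the treatment-level rate is the mean of well-level slopes
  with a bootstrap CI, not a fit to an averaged curve.
- **OCR clamping**: negative Seahorse readings are clamped to zero at
  the measurement level *before* phase averaging (clamp-then-average).
  Only the basal phase feeds the ATP-growth analysis;
  oligomycin/FCCP/antimycin-rotenone phase means are reported for
  completeness.
- **Bootstrap details**: case resampling of condition-level points
  (replicate-level resampling within conditions is available via
  `resample = "replicates"`); resamples with degenerate (constant)
  growth rates are redrawn, not dropped, so exactly `n_iter` estimates
  enter the percentiles; intervals are 2.5th/97.5th sample percentiles
  (R's default type-7 quantile). The capacity point estimate is the
  bootstrap median (mean by flag); $V_{max}$ and $\phi$ are drawn
  independently, since no joint structure for the two empirical
  distributions is available.
- **Exceedance** above a capacity line uses strict inequality — a
  measurement exactly at the ceiling is not "above" it — a conservative
  tie-break; the non-strict variant is a flag away.
- **Theoretical-vs-empirical basis**: the demand sum is natively per mg
  *dry mass* while the slope is per mg *protein*; `biomass_atp_demand()`
  reports both bases, converting by dividing by the protein mass
  fraction. Comparisons against the slope use the per-protein basis.
  The shipped organism compositions are labeled reconstructions of
  typical literature values and are configuration, not constants.

## What the synthetic generators emulate — and what they do not

`gen_flux_growth()` draws growth rates uniformly over 0.005-0.055
hr$^{-1}$ (doubling times of roughly 13 h to 6 d, spanning fast cancer
lines to slow primary-like cultures), applies the true line (defaults:
slope 68, intercept 5) with multiplicative lognormal noise of mean
exactly 1 (CV 0.10, a typical day-to-day variability for composite flux
measurements), splits total ATP into fermentation and respiration by a
logistic share rising with growth rate (0.30 to 0.85 around a midpoint
of 0.025 hr$^{-1}$) — mirroring the observation that lactate production
correlates strongly with growth while O$_2$ consumption correlates
weakly — and inverts the split through the yield model so the
stoichiometry stage round-trips exactly.

`gen_growth_plate()` produces 96-well plates seeded at 400 nuclei,
imaged daily for 6 days, growing at 0.03 hr$^{-1}$ with confluence at
60,000 nuclei. Saturation is a *soft minimum* between the exponential
trajectory and the capacity (sharpness exponent 6), not a textbook
logistic: contact inhibition in a monolayer bites abruptly near
confluence, whereas a logistic bends the curve substantially from half
capacity onward — which no plateau-detection rule applied to daily
sampling could excise. Noisy counts are rounded to integers; at zero
noise the exact expectation curve is returned so that exact-recovery
tests are meaningful to machine precision.

`gen_perturbation()` implements four mechanistic scenarios: LDH
inhibition (fermentation scaled down with 30% respiratory compensation,
growth sliding down the line), ETC inhibition (respiration ablated,
fermentation compensating fully at unchanged growth), translation
inhibition (growth and total ATP moving down the line together), and an
ATP-hydrolysis sink (total ATP up, growth halved — an off-line upward
shift that a prediction band flags as "above").

The generators do **not** emulate: plate position effects beyond a
uniform edge deficit, instrument drift or batch structure, correlated
noise between lactate and O$_2$ measurements of the same condition,
non-glucose carbon sources, or growth-rate-dependent cell size change.
Passing tests therefore demonstrate the pipeline's correctness and
statistical calibration under clean-but-noisy conditions, not
robustness to structured artifacts in real plate data.

## Validation problem sizes

The shipped tests fit the entire suite in well under a minute: 200
generator seeds × 10,000 bootstrap iterations for slope-CI coverage;
500 datasets × 20 fresh points (10,000 points) for prediction-band
coverage; 1,000-value inputs for the quadratic counting oracles;
96-well × 7-timepoint plates for growth fitting. These sizes were
chosen so that Monte-Carlo error is small relative to the tolerances
being asserted (e.g. a binomial SE of ~1.5 percentage points on a
200-run coverage estimate against a ±5-point tolerance).

## Known limitations

- With only 12 condition-level points, the percentile bootstrap is
  known to undercover slightly; measured slope-CI coverage under the
  default generator is ~0.90-0.91 rather than 0.95. Users wanting
  tighter calibration at small n should prefer more conditions or a
  BCa-style correction (not implemented).
- The prediction band assumes Gaussian homoscedastic residuals;
  empirical coverage under the generator's multiplicative noise is
  ~0.94, acceptably close at these noise levels but expected to degrade
  at higher CVs.
- The saturation rule needs three or more timepoints and can retain one
  shoulder point when sampling happens to straddle the onset of
  confluence, biasing fits slightly downward; denser sampling or a
  stricter `plateau_tolerance` mitigates this.
- Capacity estimates are only as good as the supplied $V_{max}$ and
  $\phi$ samples; the package deliberately does not estimate them from
  proteomics data.
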