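# Ground-truth synthetic data for end-to-end validation ------------------

#' Configuration for the synthetic-data generators
#'
#' Collects every knob the generators use, with defaults emulating the
#' mammalian-cell study conditions: twelve conditions, an ATP-growth line
#' with slope 68 umol ATP per mg protein and a small positive maintenance
#' intercept, 10% coefficient-of-variation multiplicative noise, growth
#' rates spanning doubling times of roughly 13 h to 6 days, and a 96-well
#' plate seeded at a few hundred cells per well.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param organism `"ecoli"`, `"yeast"` or `"mammalian"`.
#' @param true_slope ATP-growth slope, umol ATP per mg protein.
#' @param true_intercept Maintenance intercept, umol (mg protein)^-1
#'   hr^-1.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise on fluxes and counts.
#' @param n_conditions Number of flux-growth conditions.
#' @param growth_range Range of growth rates sampled, hr^-1.
#' @param glycolytic_share Parameters of the logistic mapping from growth
#'   rate to the glycolytic fraction of ATP production (list with `min`,
#'   `max`, `steepness`, `midpoint`); the share rises with growth rate.
#' @param n_rows,n_cols Plate geometry.
#' @param n0 Nuclei seeded per well.
#' @param mu True growth rate of plate wells, hr^-1.
#' @param capacity Saturation (confluence) nuclei count of a well.
#' @param saturation_sharpness Exponent of the soft-minimum between the
#'   exponential trajectory and the capacity; larger values make the
#'   transition to plateau more abrupt.
#' @param times_hr Imaging times, hours.
#' @param n_low_count_wells Interior wells deliberately seeded far below
#'   the 100-nuclei quality threshold, to exercise the low-count filter.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1, organism = "mammalian",
                             true_slope = 68, true_intercept = 5,
                             noise_cv = 0.10, n_conditions = 12,
                             growth_range = c(0.005, 0.055),
                             glycolytic_share = list(min = 0.3, max = 0.85,
                                                     steepness = 120,
                                                     midpoint = 0.025),
                             n_rows = 8, n_cols = 12, n0 = 400, mu = 0.03,
                             capacity = 60000, saturation_sharpness = 6,
                             times_hr = seq(0, 144, by = 24),
                             n_low_count_wells = 2) {
  check_number(seed, "seed")
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(n_conditions, "n_conditions", min = 3)
  structure(
    list(seed = seed, organism = organism, true_slope = true_slope,
         true_intercept = true_intercept, noise_cv = noise_cv,
         n_conditions = n_conditions, growth_range = growth_range,
         glycolytic_share = glycolytic_share, n_rows = n_rows,
         n_cols = n_cols, n0 = n0, mu = mu, capacity = capacity,
         saturation_sharpness = saturation_sharpness,
         times_hr = times_hr, n_low_count_wells = n_low_count_wells),
    class = "generator_config"
  )
}

# lognormal multiplicative noise with mean exactly 1
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

glycolytic_share_at <- function(share, mu) {
  share$min + (share$max - share$min) /
    (1 + exp(-share$steepness * (mu - share$midpoint)))
}

#' Generate a flux-growth table with known linear ATP-growth truth
#'
#' Growth rates are drawn uniformly over the configured range; the true
#' total ATP production rate is `true_slope * mu + true_intercept` times
#' multiplicative lognormal noise (mean 1, CV `noise_cv`). The total is
#' split into fermentative and respiratory components by the logistic
#' glycolytic-share model and inverted through the organism's yield
#' stoichiometry, so [atp_from_fluxes()] on the generated fluxes
#' reproduces the generated totals exactly. Yeast conditions excrete
#' ethanol; *E. coli* and mammalian conditions excrete lactate.
#'
#' @param config A [generator_config()].
#' @return Tibble with columns `organism`, `condition`,
#'   `growth_rate_per_hr`, `lactate`, `ethanol`, `acetate`, `o2` and a
#'   `"truth"` attribute (list: `true_slope`, `true_intercept`, `mu`,
#'   `atp_total`, `glycolytic_share`, `seed`).
#' @export
gen_flux_growth <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  model <- preset_yield_model(config$organism)
  n <- config$n_conditions
  out <- with_seed(config$seed, {
    mu <- sort(runif(n, config$growth_range[1L], config$growth_range[2L]))
    total <- (config$true_slope * mu + config$true_intercept) *
      lognormal_noise(n, config$noise_cv)
    share <- glycolytic_share_at(config$glycolytic_share, mu)
    glycolytic <- share * total
    respiratory <- (1 - share) * total
    ferment <- glycolytic # 1 ATP per excreted lactate/ethanol
    o2 <- respiratory / atp_per_o2(model)
    tab <- tibble::tibble(
      organism = config$organism,
      condition = sprintf("cond%02d", seq_len(n)),
      growth_rate_per_hr = mu,
      lactate = if (config$organism == "yeast") 0 else ferment,
      ethanol = if (config$organism == "yeast") ferment else 0,
      acetate = 0,
      o2 = o2
    )
    attr(tab, "truth") <- list(
      true_slope = config$true_slope,
      true_intercept = config$true_intercept,
      mu = mu, atp_total = total, glycolytic_share = share,
      seed = config$seed
    )
    tab
  })
  out
}

#' Generate a microplate nuclei-count time series with known growth rate
#'
#' Interior wells grow exponentially at the configured rate with
#' logistic saturation at the confluence capacity and multiplicative
#' lognormal count noise; edge wells grow 20% slower (emulating the
#' evaporation edge effect the edge filter exists for); a configured
#' number of interior wells are seeded far below the 100-nuclei
#' threshold to exercise the low-count filter.
#'
#' @param config A [generator_config()].
#' @return Long tibble `well_id`, `row`, `col`, `time_hr`,
#'   `nuclei_count` (integers when `noise_cv > 0`; the exact expectation
#'   curve at zero noise), with a `"truth"` attribute (list: `mu`,
#'   `edge_mu`, `capacity`, `low_count_wells`, `seed`).
#' @export
gen_growth_plate <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    grid <- expand.grid(row = seq_len(config$n_rows),
                        col = seq_len(config$n_cols))
    grid$well_id <- sprintf("%s%02d", LETTERS[grid$row], grid$col)
    interior <- grid$row > 1 & grid$row < config$n_rows &
      grid$col > 1 & grid$col < config$n_cols
    low_ids <- sample(grid$well_id[interior],
                      min(config$n_low_count_wells, sum(interior)))
    edge_mu <- 0.8 * config$mu
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      mu_i <- if (interior[i]) config$mu else edge_mu
      n0_i <- if (grid$well_id[i] %in% low_ids) 30 else config$n0
      k <- config$capacity
      # soft-minimum saturation: near-exponential until close to
      # confluence, then a plateau at the capacity (contact inhibition
      # sets in abruptly, unlike a textbook logistic)
      x <- n0_i * exp(mu_i * config$times_hr) / k
      expected <- k * x / (1 + x^config$saturation_sharpness)^
        (1 / config$saturation_sharpness)
      counts <- expected * lognormal_noise(length(expected), config$noise_cv)
      # noisy counts are realized measurements, hence integers; at zero
      # noise the exact expectation curve is returned unrounded
      if (config$noise_cv > 0) counts <- round(counts)
      tibble::tibble(
        well_id = grid$well_id[i], row = grid$row[i], col = grid$col[i],
        time_hr = config$times_hr,
        nuclei_count = pmax(counts, 1)
      )
    })
    plate <- do.call(rbind, rows)
    attr(plate, "truth") <- list(
      mu = config$mu, edge_mu = edge_mu, capacity = config$capacity,
      low_count_wells = sort(low_ids), seed = config$seed
    )
    plate
  })
}

#' Generate a Seahorse-style OCR trace
#'
#' Three measurements per injection phase around the configured phase
#' means with additive Gaussian noise, which can produce negative raw
#' values (as real instruments do) to exercise the clamp-at-zero rule.
#'
#' @param phase_means Named numeric vector of per-minute OCR means for
#'   `basal`, `oligomycin`, `fccp1`, `fccp2`, `antimycin_rotenone`.
#' @param noise_sd Additive Gaussian SD on each measurement.
#' @param seed Integer seed.
#' @return Tibble `phase`, `measurement_index`, `value`, with a
#'   `"truth"` attribute carrying `phase_means`, `noise_sd` and `seed`.
#' @export
gen_seahorse <- function(phase_means = c(basal = 5, oligomycin = 1,
                                         fccp1 = 8, fccp2 = 8,
                                         antimycin_rotenone = 0.05),
                         noise_sd = 0, seed = 1) {
  required <- c("basal", "oligomycin", "fccp1", "fccp2", "antimycin_rotenone")
  if (!all(required %in% names(phase_means))) {
    stop("`phase_means` must name all five injection phases", call. = FALSE)
  }
  with_seed(seed, {
    tab <- do.call(rbind, lapply(required, function(ph) {
      tibble::tibble(
        phase = ph,
        measurement_index = 1:3,
        value = phase_means[[ph]] + rnorm(3, sd = noise_sd)
      )
    }))
    attr(tab, "truth") <- list(phase_means = phase_means,
                               noise_sd = noise_sd, seed = seed)
    tab
  })
}

#' Generate flux-growth points under ATP-supply or -demand perturbations
#'
#' Transforms a baseline [gen_flux_growth()] dataset according to the
#' mechanism of each perturbation:
#' \describe{
#'   \item{`ldh_inhibition`}{Fermentative flux is scaled down by the dose
#'     with partial (30% of the lost ATP) respiratory compensation;
#'     growth slides down the true line to match the reduced total.}
#'   \item{`etc_inhibition`}{Respiration is abolished and fermentation
#'     compensates fully, keeping the total on the line at unchanged
#'     growth.}
#'   \item{`translation_inhibition`}{Growth is scaled down by the dose
#'     and the total ATP follows the true line downward.}
#'   \item{`atp_sink`}{An ATP-hydrolysis sink adds a fixed extra demand
#'     (`sink_extra`, umol mg^-1 hr^-1) to the total while growth halves
#'     - an upward, off-line shift.}
#' }
#'
#' @param config A [generator_config()] for the baseline.
#' @param scenario One of the four perturbations above.
#' @param dose Fractional inhibition in `[0, 1]` (ignored by
#'   `atp_sink`); `dose = 0` returns the baseline unchanged.
#' @param sink_extra Extra ATP demand for `atp_sink`.
#' @return Tibble like [gen_flux_growth()] plus `scenario` and `dose`
#'   columns and ATP components `atp_glycolytic`, `atp_respiratory`,
#'   `atp_total`; `"truth"` attribute as in the baseline.
#' @export
gen_perturbation <- function(config = generator_config(),
                             scenario = c("ldh_inhibition", "etc_inhibition",
                                          "translation_inhibition",
                                          "atp_sink"),
                             dose = 0.5, sink_extra = 10) {
  scenario <- match.arg(scenario)
  check_number(dose, "dose", min = 0)
  if (dose > 1) stop_bad_arg("dose", "must lie in [0, 1]")
  base <- gen_flux_growth(config)
  truth <- attr(base, "truth")
  model <- preset_yield_model(config$organism)
  atp <- atp_from_fluxes(lactate_rate = base$lactate,
                         ethanol_rate = base$ethanol,
                         acetate_rate = base$acetate,
                         o2_rate = base$o2, model = model)
  glyc <- atp$glycolytic
  resp <- atp$respiratory
  mu <- base$growth_rate_per_hr
  s <- config$true_slope
  b <- config$true_intercept
  if (dose > 0 || scenario == "atp_sink") {
    switch(scenario,
      ldh_inhibition = {
        lost <- dose * glyc
        glyc <- glyc - lost
        resp <- resp + 0.3 * lost
        mu <- pmax((glyc + resp - b) / s, 0)
      },
      etc_inhibition = {
        glyc <- glyc + dose * resp
        resp <- (1 - dose) * resp
      },
      translation_inhibition = {
        mu <- (1 - dose) * mu
        scale <- (s * mu + b) / (glyc + resp)
        glyc <- glyc * scale
        resp <- resp * scale
      },
      atp_sink = {
        extra_share <- glycolytic_share_at(config$glycolytic_share, mu)
        glyc <- glyc + extra_share * sink_extra
        resp <- resp + (1 - extra_share) * sink_extra
        mu <- mu / 2
      }
    )
  }
  ferment <- glyc
  out <- tibble::tibble(
    organism = base$organism,
    condition = base$condition,
    scenario = scenario,
    dose = dose,
    growth_rate_per_hr = mu,
    lactate = if (config$organism == "yeast") 0 else ferment,
    ethanol = if (config$organism == "yeast") ferment else 0,
    acetate = 0,
    o2 = resp / atp_per_o2(model),
    atp_glycolytic = glyc,
    atp_respiratory = resp,
    atp_total = glyc + resp
  )
  attr(out, "truth") <- truth
  out
}
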