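test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- generator_config(seed = 13)
  expect_identical(gen_flux_growth(cfg), gen_flux_growth(cfg))
  expect_identical(gen_growth_plate(cfg), gen_growth_plate(cfg))
  expect_identical(gen_seahorse(noise_sd = 1, seed = 13),
                   gen_seahorse(noise_sd = 1, seed = 13))
  expect_identical(gen_perturbation(cfg, "atp_sink"),
                   gen_perturbation(cfg, "atp_sink"))
})

test_that("generators restore the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(gen_flux_growth(generator_config(seed = 2)))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise flux tables return the generating line exactly", {
  cfg <- generator_config(seed = 3, noise_cv = 0)
  fg <- gen_flux_growth(cfg)
  m <- preset_yield_model("mammalian")
  atp <- atp_from_fluxes(lactate_rate = fg$lactate, o2_rate = fg$o2, model = m)
  fit <- fit_line(tibble::tibble(growth_rate = fg$growth_rate_per_hr,
                                 atp_total = atp$total))
  expect_equal(fit$slope, 68, tolerance = 1e-9)
  expect_equal(fit$intercept, 5, tolerance = 1e-9)
})

test_that("flux splitting inverts exactly through the yield model", {
  for (org in c("ecoli", "yeast", "mammalian")) {
    cfg <- generator_config(seed = 6, organism = org)
    fg <- gen_flux_growth(cfg)
    truth <- attr(fg, "truth")
    m <- preset_yield_model(org)
    atp <- atp_from_fluxes(lactate_rate = fg$lactate,
                           ethanol_rate = fg$ethanol,
                           acetate_rate = fg$acetate,
                           o2_rate = fg$o2, model = m)
    expect_equal(atp$total, truth$atp_total, tolerance = 1e-12)
    if (org == "yeast") expect_true(all(fg$lactate == 0))
    if (org != "yeast") expect_true(all(fg$ethanol == 0))
  }
})

test_that("plates carry edge deficits and seeded low-count wells", {
  cfg <- generator_config(seed = 19, noise_cv = 0, capacity = 1e9)
  plate <- gen_growth_plate(cfg)
  truth <- attr(plate, "truth")
  expect_length(truth$low_count_wells, 2)
  low <- plate[plate$well_id %in% truth$low_count_wells, ]
  expect_true(all(tapply(low$nuclei_count, low$well_id, min) < 100))
  # edge wells grow slower than interior wells
  edge <- plate[plate$row == 1 & plate$col == 5, ]
  f_edge <- fit_growth(edge[, c("time_hr", "nuclei_count")])
  expect_equal(f_edge$mu, truth$edge_mu, tolerance = 1e-10)
})

test_that("seahorse generator hits configured phase means at zero noise", {
  tr <- gen_seahorse(noise_sd = 0, seed = 1)
  d <- cell_descriptor("X", 2000, 5e-10)
  out <- process_seahorse(tr, 1e6, d)
  expect_equal(out$basal_ocr, 5 * 60)
  expect_equal(unname(out$phase_means[["oligomycin"]]), 1)
  tr_neg <- gen_seahorse(phase_means = c(basal = 5, oligomycin = 1,
                                         fccp1 = 8, fccp2 = 8,
                                         antimycin_rotenone = 0),
                         noise_sd = 0.5, seed = 2)
  out2 <- process_seahorse(tr_neg, 1e6, d)
  expect_gte(unname(out2$phase_means[["antimycin_rotenone"]]), 0)
})

test_that("perturbation scenarios shift points in the expected directions", {
  cfg <- generator_config(seed = 8, noise_cv = 0)
  base <- gen_perturbation(cfg, "ldh_inhibition", dose = 0)
  fg <- gen_flux_growth(cfg)
  expect_equal(base$growth_rate_per_hr, fg$growth_rate_per_hr)
  expect_equal(base$lactate, fg$lactate)

  # band from a realistically noisy baseline (a zero-noise baseline has a
  # zero-width band, making classification a floating-point coin flip)
  noisy <- gen_perturbation(generator_config(seed = 8), "ldh_inhibition",
                            dose = 0)
  fit <- fit_line(tibble::tibble(growth_rate = noisy$growth_rate_per_hr,
                                 atp_total = noisy$atp_total))
  band <- prediction_band(fit, noisy$growth_rate_per_hr, level = 0.95)

  trans <- gen_perturbation(cfg, "translation_inhibition", dose = 0.5)
  expect_equal(trans$atp_total,
               68 * trans$growth_rate_per_hr + 5, tolerance = 1e-9)
  for (i in seq_len(nrow(trans))) {
    expect_identical(classify_point(band, trans[i, ]), "inside")
  }

  etc <- gen_perturbation(cfg, "etc_inhibition", dose = 1)
  expect_true(all(etc$atp_respiratory == 0))
  expect_equal(etc$atp_total, base$atp_total, tolerance = 1e-12)
  expect_identical(classify_point(band, etc[5, ], axis = "total_atp"),
                   "inside")
  expect_identical(classify_point(band, etc[5, ], axis = "respiratory"),
                   "below")

  sink <- gen_perturbation(cfg, "atp_sink", sink_extra = 10)
  expect_true(all(sink$atp_total > base$atp_total))
  expect_true(all(sink$growth_rate_per_hr < base$growth_rate_per_hr))
  cls <- vapply(seq_len(nrow(sink)),
                function(i) classify_point(band, sink[i, ]), character(1))
  expect_true(all(cls == "above"))

  ldh <- gen_perturbation(cfg, "ldh_inhibition", dose = 0.6)
  expect_true(all(ldh$atp_glycolytic < base$atp_glycolytic))
  expect_true(all(ldh$atp_respiratory > base$atp_respiratory))
  expect_true(all(ldh$growth_rate_per_hr < base$growth_rate_per_hr))
  expect_error(gen_perturbation(cfg, "heat_shock"))
})
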