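test_that("exact lines are recovered exactly", {
  pts <- tibble::tibble(growth_rate = c(0.01, 0.03, 0.05),
                        atp_total = 68 * c(0.01, 0.03, 0.05) + 5)
  fit <- fit_line(pts)
  expect_equal(fit$slope, 68)
  expect_equal(fit$intercept, 5)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_line(tibble::tibble(growth_rate = rep(0.02, 4),
                                       atp_total = 1:4)), "unidentifiable")
  expect_error(fit_line(pts[1:2, ]), "at least 3")
})

test_that("Pearson p-value matches the exact t transform", {
  set.seed(23)
  x <- runif(15, 0.01, 0.06)
  y <- 68 * x + 5 + rnorm(15, sd = 0.8)
  fit <- fit_line(tibble::tibble(growth_rate = x, atp_total = y))
  ct <- stats::cor.test(x, y)
  expect_equal(fit$pearson_r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(fit$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("the fit is equivariant under rescaling of ATP values", {
  set.seed(31)
  x <- runif(10, 0.01, 0.06)
  y <- 68 * x + 5 + rnorm(10, sd = 0.5)
  f1 <- fit_line(tibble::tibble(growth_rate = x, atp_total = y))
  f2 <- fit_line(tibble::tibble(growth_rate = x, atp_total = 3 * y))
  expect_equal(f2$slope, 3 * f1$slope)
  expect_equal(f2$intercept, 3 * f1$intercept)
  expect_equal(f2$r_squared, f1$r_squared)
})

test_that("bootstrap CIs are deterministic and contain the estimate", {
  cfg <- generator_config(seed = 44)
  fg <- gen_flux_growth(cfg)
  m <- preset_yield_model("mammalian")
  atp <- atp_from_fluxes(lactate_rate = fg$lactate, o2_rate = fg$o2, model = m)
  pts <- tibble::tibble(growth_rate = fg$growth_rate_per_hr,
                        atp_total = atp$total)
  b1 <- bootstrap_fit(pts, n_iter = 2000, seed = 7)
  b2 <- bootstrap_fit(pts, n_iter = 2000, seed = 7)
  expect_identical(b1$slope_ci, b2$slope_ci)
  expect_identical(b1$intercept_ci, b2$intercept_ci)
  expect_lte(b1$slope_ci[1], b1$slope)
  expect_gte(b1$slope_ci[2], b1$slope)
  # generator truth recovered within the fit's own CI
  expect_lte(b1$slope_ci[1], 68)
  expect_gte(b1$slope_ci[2], 68)
})

test_that("collinear repeated points give a zero-width CI", {
  pts <- tibble::tibble(
    growth_rate = rep(c(0.01, 0.05), each = 3),
    atp_total = 68 * rep(c(0.01, 0.05), each = 3) + 5
  )
  b <- bootstrap_fit(pts, n_iter = 500, seed = 3)
  expect_equal(b$slope_ci, c(68, 68))
  expect_equal(b$intercept_ci, c(5, 5))
})

test_that("replicate-level resampling fits condition means", {
  set.seed(12)
  conds <- rep(sprintf("c%d", 1:6), each = 4)
  mu <- rep(seq(0.01, 0.06, length.out = 6), each = 4) + rnorm(24, sd = 5e-4)
  atp <- 68 * mu + 5 + rnorm(24, sd = 0.4)
  pts <- tibble::tibble(condition = conds, growth_rate = mu, atp_total = atp)
  b <- bootstrap_fit(pts, n_iter = 500, seed = 2, resample = "replicates")
  expect_equal(b$n, 6L)
  expect_equal(b$slope, 68, tolerance = 0.25)
  expect_lte(b$slope_ci[1], b$slope)
})

test_that("prediction band matches the classical OLS interval", {
  set.seed(71)
  x <- runif(12, 0.01, 0.06)
  y <- 68 * x + 5 + rnorm(12, sd = 0.6)
  fit <- fit_line(tibble::tibble(growth_rate = x, atp_total = y))
  xs <- seq(0.005, 0.07, length.out = 9)
  band <- prediction_band(fit, xs, level = 0.95)
  lmfit <- lm(y ~ x)
  ref <- predict(lmfit, newdata = data.frame(x = xs),
                 interval = "prediction", level = 0.95)
  expect_equal(band$fit, unname(ref[, "fit"]), tolerance = 1e-10)
  expect_equal(band$lower, unname(ref[, "lwr"]), tolerance = 1e-10)
  expect_equal(band$upper, unname(ref[, "upr"]), tolerance = 1e-10)
})

test_that("the band is narrowest at the mean and collapses at level 0", {
  set.seed(72)
  x <- runif(12, 0.01, 0.06)
  y <- 68 * x + 5 + rnorm(12, sd = 0.6)
  fit <- fit_line(tibble::tibble(growth_rate = x, atp_total = y))
  xs <- c(mean(x), mean(x) + 0.01, mean(x) + 0.03)
  band <- prediction_band(fit, xs, level = 0.95)
  widths <- band$upper - band$lower
  expect_true(all(diff(widths) > 0))
  flat <- prediction_band(fit, xs, level = 0)
  expect_equal(flat$lower, flat$fit)
  expect_equal(flat$upper, flat$fit)
  expect_error(prediction_band(fit, xs, level = 1), "level")
})

test_that("points are classified consistently against the band", {
  pts <- tibble::tibble(growth_rate = seq(0.01, 0.06, length.out = 8))
  pts$atp_total <- 68 * pts$growth_rate + 5 +
    c(0.3, -0.2, 0.1, -0.4, 0.2, -0.1, 0.4, -0.3)
  fit <- fit_line(pts)
  band <- prediction_band(fit, pts$growth_rate, level = 0.95)
  on_line <- list(growth_rate = 0.03, atp_total = fit$intercept + 68 * 0.03)
  expect_identical(classify_point(band, on_line), "inside")
  lim <- prediction_band(fit, 0.03, level = 0.95)
  above <- list(growth_rate = 0.03, atp_total = lim$upper + 1e-9)
  expect_identical(classify_point(band, above), "above")
  below <- list(growth_rate = 0.03, atp_total = lim$lower - 1e-9)
  expect_identical(classify_point(band, below), "below")
  # a point cannot be above and below at once: bounds are ordered
  expect_true(all(band$upper >= band$lower))
})
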