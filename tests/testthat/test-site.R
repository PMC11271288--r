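# small regular series builder with populated acclimation columns
make_series <- function(n_days = 15, t_fun = NULL, lai = 1) {
  ts <- seq(as.POSIXct("2021-06-01", tz = "UTC"), by = 1800,
            length.out = n_days * 48)
  t_air <- if (is.null(t_fun)) rep(290, length(ts)) else t_fun(ts)
  tm <- trailing_means(ts, t_air)
  data.frame(timestamp = ts, t_air = t_air, ppfd = 1000,
             lai = lai, T24 = tm$T24, T240 = tm$T240)
}

test_that("canopy scaling multiplies leaf factors by 1.5", {
  expect_equal(canopy_ef(12.0), 18.0)
  expect_equal(canopy_ef(6.5), 9.75)
  expect_equal(canopy_ef(1.0), 1.5)
  expect_error(canopy_ef(-2), "positive")
})

test_that("model_flux reduces to canopy EF under unit conditions", {
  ser <- make_series()
  ser$t_air <- rep(303.15, nrow(ser))
  ser$T240 <- rep(288.15, nrow(ser))
  ser$T24 <- rep(288.15, nrow(ser))
  pft <- site_pft("sedge", 12, "sedge", cover_fraction = 1)
  flux <- model_flux(ser, list(pft), g_others = 1)
  # gamma_sedge(303.15, 288.15) = e_opt_sg(288.15) = 1, LAI/LAImax = 1
  expect_equal(flux, rep(pft$canopy_ef, nrow(ser)))
})

test_that("model_flux is linear in cover fractions and LAI", {
  ser <- make_series(t_fun = function(ts) {
    285 + 5 * sin(seq_along(ts) / 37)
  }, lai = NA)
  ser$lai <- seq(0.4, 1, length.out = nrow(ser))
  p1 <- site_pft("sedge", 12, "sedge", cover_fraction = 0.3)
  p2 <- site_pft("shrub", 6.5, "willow", cover_fraction = 0.2)
  f12 <- model_flux(ser, list(p1, p2))
  f1 <- model_flux(ser, list(p1))
  f2 <- model_flux(ser, list(p2))
  expect_equal(f12, f1 + f2)          # superposition over PFTs
  double <- lapply(list(p1, p2), function(p) {
    p$cover_fraction <- p$cover_fraction * 2; p
  })
  expect_equal(model_flux(ser, double), 2 * f12)  # linear in CF
  zero_lai <- ser
  zero_lai$lai <- 0
  expect_error(model_flux(zero_lai, list(p1)), "LAI")
  i <- 500  # past the acclimation spin-up
  one_zero <- ser
  one_zero$lai[i] <- 0
  expect_equal(model_flux(one_zero, list(p1))[i], 0)  # zero LAI, zero flux
})

test_that("spin-up rows yield NA flux", {
  ser <- make_series()
  pft <- site_pft("sedge", 12, "sedge", cover_fraction = 0.5)
  flux <- model_flux(ser, list(pft))
  expect_true(all(is.na(flux[seq_len(480)])))
  expect_true(all(!is.na(flux[-seq_len(480)])))
})

test_that("noise-free cover fractions are recovered exactly", {
  sim <- gen_site(synthetic_config(seed = 5, site_noise_frac = 0),
                  n_days = 30)
  fit <- fit_cover_fractions(sim$series, sim$pfts)
  expect_equal(unname(fit$coef), c(0.25, 0.10), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-6)
})

test_that("noisy cover fractions are recovered within 0.03", {
  sim <- gen_site(synthetic_config(seed = 6), n_days = 60)
  fit <- fit_cover_fractions(sim$series, sim$pfts)
  expect_lt(max(abs(fit$coef - c(0.25, 0.10))), 0.03)
  expect_gt(fit$r_squared, 0.8)
})

test_that("fit-ei mode recovers total capacities for the default model", {
  cfg <- synthetic_config(seed = 8, site_noise_frac = 0)
  sim <- gen_site(cfg, n_days = 30)
  fit <- fit_cover_fractions(sim$series, sim$pfts, mode = "fit-ei")
  want <- c(canopy_ef(12) * 0.25, canopy_ef(6.5) * 0.10)
  expect_equal(unname(fit$coef), want, tolerance = 1e-5)
})

test_that("zero observed flux drives all fractions to zero", {
  sim <- gen_site(synthetic_config(seed = 9, site_noise_frac = 0),
                  n_days = 25)
  sim$series$flux <- 0
  fit <- fit_cover_fractions(sim$series, sim$pfts)
  expect_equal(unname(fit$coef), c(0, 0))
})

test_that("the PPFD filter is strict and only drops ppfd <= threshold", {
  sim <- gen_site(synthetic_config(seed = 10), n_days = 25)
  fit <- fit_cover_fractions(sim$series, sim$pfts, ppfd_min = 300)
  ok <- sim$series$ppfd > 300 & !is.na(sim$series$T240) &
    !is.na(sim$series$flux)
  expect_equal(fit$n_obs, sum(ok))
  # rows at or below the threshold carry no weight: zeroing them changes
  # nothing
  mangled <- sim$series
  mangled$flux[mangled$ppfd <= 300] <- -999
  fit2 <- fit_cover_fractions(mangled, sim$pfts, ppfd_min = 300)
  expect_equal(fit2$coef, fit$coef)
})

test_that("collinear PFT bases are rejected with advice", {
  sim <- gen_site(synthetic_config(seed = 12, site_noise_frac = 0),
                  n_days = 25)
  twins <- list(site_pft("a", 12, "sedge"), site_pft("b", 12, "sedge"))
  expect_error(fit_cover_fractions(sim$series, twins), "collinear")
})

test_that("a sum-to-one constraint caps the fitted fractions", {
  sim <- gen_site(synthetic_config(seed = 13, site_noise_frac = 0,
                                   cf_sedge = 0.9, cf_shrub = 0.6),
                  n_days = 25)
  fit <- fit_cover_fractions(sim$series, sim$pfts, sum_to_one = TRUE)
  expect_lte(sum(fit$coef), 1 + 1e-8)
})

test_that("evaluate_fit reports the documented metrics", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- evaluate_fit(x, x)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  shifted <- evaluate_fit(x + 2, x)
  expect_equal(shifted$r_squared, 1)
  expect_equal(shifted$rmse, 2)
  set.seed(31)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(evaluate_fit(a, b)$r_squared, 0.02)
  expect_error(evaluate_fit(1:3, 1:4), "length")
  # ss convention differs for biased predictions
  expect_lt(evaluate_fit(x + 2, x, r2_method = "ss")$r_squared, 1)
})

test_that("daily aggregation averages within calendar days", {
  ts <- seq(as.POSIXct("2021-06-01", tz = "UTC"), by = 1800,
            length.out = 96)
  m <- c(rep(1, 48), rep(3, 48))
  o <- c(rep(2, 48), rep(5, 48))
  ev <- evaluate_fit(m, o, aggregate = "daily", timestamps = ts)
  expect_equal(ev$n, 2)
  expect_equal(ev$daily$modeled, c(1, 3))
  expect_equal(ev$daily$observed, c(2, 5))
  expect_equal(ev$rmse, sqrt(mean(c(1, 4))))
})

test_that("updated model outgains the default under a heatwave", {
  cfg <- synthetic_config(seed = 14, site_noise_frac = 0)
  base <- gen_site(cfg, n_days = 40)
  hw <- gen_site(cfg, n_days = 40, heatwave_amp = 8)
  pfts_def <- lapply(hw$pfts, function(p) { p$response <- "default"; p })
  win <- which(hw$series$t_air - base$series$t_air > 4)
  upd_gain <- mean(hw$series$flux_true[win], na.rm = TRUE) /
    mean(base$series$flux_true[win], na.rm = TRUE)
  def_hw <- model_flux(hw$series, pfts_def)
  def_base <- model_flux(base$series, pfts_def)
  def_gain <- mean(def_hw[win], na.rm = TRUE) /
    mean(def_base[win], na.rm = TRUE)
  expect_gt(upd_gain, def_gain)
})
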