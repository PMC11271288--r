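make_exp <- function(Ea, EF30, temps_k = seq(288.15, 313.15, 5),
                     noise = NULL) {
  R <- 0.008314
  e <- EF30 * exp(Ea / R * (1 / 303.15 - 1 / temps_k))
  if (!is.null(noise)) e <- e * noise
  chamber_experiment("test", temps_k, e)
}

test_that("fit_arrhenius is exact on noise-free exponential data", {
  for (Ea in c(20, 76.39, 104.5, 229.5, 300)) {
    f <- fit_arrhenius(make_exp(Ea, 5.0))
    expect_equal(f$Ea, Ea, tolerance = 1e-9)
    expect_equal(f$EF30, 5.0, tolerance = 1e-9)
    expect_equal(f$r_squared, 1)
  }
})

test_that("two-point fit reproduces the closed-form slope", {
  e <- chamber_experiment("two", c(298.15, 308.15), c(1, exp(1)))
  f <- fit_arrhenius(e)
  expect_equal(f$Ea, 0.008314 / (1 / 298.15 - 1 / 308.15),
               tolerance = 1e-10)
})

test_that("steps above t_max are excluded and counted", {
  temps <- celsius_to_kelvin(c(15, 20, 25, 30, 35, 40))
  f <- fit_arrhenius(make_exp(100, 5, temps_k = temps), t_max = 308.15)
  expect_equal(f$n_points, 5)
  expect_equal(f$n_excluded, 1)
  expect_equal(max(f$t_range), celsius_to_kelvin(35))
})

test_that("zero-emission steps are dropped with a warning", {
  e <- chamber_experiment("z", c(288.15, 298.15, 308.15), c(0, 1, 3))
  expect_warning(f <- fit_arrhenius(e), "dropped")
  expect_equal(f$n_points, 2)
  only_zero <- chamber_experiment("z2", c(288.15, 298.15), c(0, 1))
  expect_warning(expect_error(fit_arrhenius(only_zero), "usable"))
})

test_that("chamber_experiment validates steps and applies blanks", {
  expect_error(chamber_experiment("x", c(300, 300), c(1, 2)), "distinct")
  expect_error(chamber_experiment("x", c(300, 290), c(1, 2)), "ascending")
  expect_error(chamber_experiment("x", c(290, 300), c(-1, 2)), ">= 0")
  expect_warning(
    e <- chamber_experiment("b", c(290, 300), c(0.5, 2),
                            blank_rate = c(1, 1)),
    "floored")
  expect_equal(e$steps$emission, c(0, 1))
})

test_that("q10_from_steps matches measured ratios and the q10 utility", {
  e <- chamber_experiment("r", c(298.15, 308.15), c(1, 3.2))
  expect_equal(q10_from_steps(e), 3.2)
  flat <- chamber_experiment("f", c(298.15, 308.15), c(2, 2))
  expect_equal(q10_from_steps(flat), 1)
  # cross-module consistency: steps sampled from the sedge curve
  curve <- function(T) gamma_t_sedge(T, 288.15)
  temps <- seq(288.15, 308.15, 5)
  samp <- chamber_experiment("s", temps, curve(temps))
  expect_equal(q10_from_steps(samp), q10(curve))
  # closed form with Ea = c_sg(288.15) = 104.5 over the 25-35 C bracket
  expect_equal(q10_from_steps(samp), 3.9278, tolerance = 1e-4)
  expect_error(q10_from_steps(make_exp(100, 5, c(288.15, 293.15))),
               "no step within")
})

test_that("lag correlation pins an exactly constructed 10-day dependence", {
  set.seed(42)
  n <- 24
  hists <- lapply(seq_len(n), function(i) 285 + rnorm(15, 0, 3))
  ten_day <- vapply(hists, function(h) mean(h[1:10]), 1)
  fits <- lapply(seq_len(n), function(i) {
    structure(list(Ea = 400 - 1.0 * ten_day[i],
                   EF30 = exp(0.1 * ten_day[i])), class = "arrhenius_fit")
  })
  hc <- history_correlation(fits, hists)
  expect_equal(as.integer(hc$best_lag_ea), 10L)
  expect_equal(as.integer(hc$best_lag_ef), 10L)
  expect_equal(abs(hc$table$r_ea[10]), 1)
})

test_that("lag selection finds a 10-day dependence in most replicates", {
  hits <- 0
  reps <- 40
  for (s in seq_len(reps)) {
    set.seed(1000 + s)
    n <- 24
    hists <- lapply(seq_len(n), function(i) 285 + rnorm(15, 0, 3))
    ten_day <- vapply(hists, function(h) mean(h[1:10]), 1)
    fits <- lapply(seq_len(n), function(i) {
      structure(list(Ea = 400 - 1.0 * ten_day[i] + rnorm(1, 0, 0.3),
                     EF30 = exp(0.1 * ten_day[i])),
                class = "arrhenius_fit")
    })
    hc <- history_correlation(fits, hists)
    if (identical(as.integer(hc$best_lag_ea), 10L)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("null responses yield no significant lag", {
  set.seed(99)
  n <- 20
  hists <- lapply(seq_len(n), function(i) 285 + rnorm(15, 0, 3))
  fits <- lapply(seq_len(n), function(i) {
    structure(list(Ea = rnorm(1, 150, 20), EF30 = rlnorm(1, 1, 0.3)),
              class = "arrhenius_fit")
  })
  hc <- history_correlation(fits, hists)
  expect_false(isTRUE(attr(hc$best_lag_ea, "significant")))
  expect_true(max(abs(hc$table$r_ea), na.rm = TRUE) < 0.6)
})

test_that("history_correlation enforces its preconditions", {
  f <- structure(list(Ea = 100, EF30 = 5), class = "arrhenius_fit")
  h <- rep(285, 15)
  expect_error(history_correlation(list(f, f), list(h, h)), "at least 3")
  expect_error(history_correlation(list(f, f, f),
                                   list(h, h, rep(285, 10))),
               ">= 15")
  # constant predictor reported as missing, not an error
  fits <- list(structure(list(Ea = 90, EF30 = 1), class = "arrhenius_fit"),
               structure(list(Ea = 100, EF30 = 2), class = "arrhenius_fit"),
               structure(list(Ea = 110, EF30 = 3), class = "arrhenius_fit"))
  hc <- history_correlation(fits, list(h, h, h))
  expect_true(all(is.na(hc$table$r_ea)))
})

test_that("fit_acclimation recovers exact acclimation coefficients", {
  T240 <- seq(282.15, 294.15, 2)
  ea <- data.frame(T240 = T240, Ea = c_sg(T240))
  ef <- data.frame(T240 = T240, EF30 = 12 * e_opt_sg(T240))
  p <- fit_acclimation(ea, ef)
  expect_equal(p$C_amp, 9.5, tolerance = 1e-6)
  expect_equal(p$C_rate, 0.53, tolerance = 1e-6)
  expect_equal(p$EF_rate, 0.12, tolerance = 1e-10)
  expect_equal(attr(p, "EF30_ref"), 12, tolerance = 1e-8)
})

test_that("fit_acclimation enforces spread and positivity", {
  T240 <- rep(288.15, 5)
  ea <- data.frame(T240 = T240, Ea = c_sg(T240))
  ef <- data.frame(T240 = T240, EF30 = e_opt_sg(T240))
  expect_error(fit_acclimation(ea, ef), "span")
  ea2 <- data.frame(T240 = c(283, 288), Ea = c(200, 105))
  ef2 <- data.frame(T240 = c(283, 288), EF30 = c(1, 2))
  expect_error(fit_acclimation(ea2, ef2), "at least 3")
})

test_that("fitted Ea falls and EF30 rises with T240 on synthetic sedges", {
  exps <- gen_chamber(synthetic_config(seed = 21, n_experiments = 15))
  fits <- lapply(exps, fit_arrhenius)
  tr <- attr(exps, "truth")
  ea <- vapply(fits, function(f) f$Ea, 1)
  ef <- vapply(fits, function(f) f$EF30, 1)
  expect_lt(cor(tr$T240, ea), -0.85)
  expect_gt(cor(tr$T240, ef), 0.85)
})
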