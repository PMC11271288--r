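#' Construct a leaf-chamber temperature-ramp experiment
#'
#' One plant's stepwise temperature-ramp measurement: emission rate at each
#' leaf-temperature step, the chamber PPFD, and the daily mean air
#' temperatures of the preceding days (day 1 = most recent) used to relate
#' fitted parameters to temperature history.
#'
#' @param species_label Species or sample label.
#' @param step_temp Leaf temperature at each step, K, ascending.
#' @param emission_rate Mean isoprene emission at each step,
#'   nmol m^-2 s^-1, non-negative.
#' @param ppfd Chamber photosynthetic photon flux density,
#'   umol m^-2 s^-1 (metadata).
#' @param prior_daily_means Daily mean air temperatures for the preceding
#'   days, K, most recent first.
#' @param blank_rate Optional chamber-blank emission per step; when given it
#'   is subtracted and negative results floored at zero with a warning.
#' @return An object of class `chamber_experiment`.
#' @export
chamber_experiment <- function(species_label, step_temp, emission_rate,
                               ppfd = 1000, prior_daily_means = numeric(),
                               blank_rate = NULL) {
  if (length(step_temp) != length(emission_rate)) {
    stop("step_temp and emission_rate must have the same length")
  }
  if (length(unique(step_temp)) < 2) {
    stop("need at least 2 steps with distinct temperatures")
  }
  if (is.unsorted(step_temp, strictly = FALSE)) {
    stop("steps must be sorted ascending in temperature")
  }
  .check_temperature(step_temp, "step temperature")
  if (!is.null(blank_rate)) {
    if (length(blank_rate) != length(emission_rate)) {
      stop("blank_rate must match emission_rate in length")
    }
    emission_rate <- emission_rate - blank_rate
    if (any(emission_rate < 0)) {
      warning("blank subtraction produced negative emission; floored at 0")
      emission_rate <- pmax(emission_rate, 0)
    }
  }
  if (any(emission_rate < 0)) stop("emission rates must be >= 0")
  structure(
    list(species_label = species_label,
         steps = data.frame(temp = step_temp, emission = emission_rate),
         ppfd = ppfd,
         prior_daily_means = prior_daily_means),
    class = "chamber_experiment"
  )
}

#' @export
print.chamber_experiment <- function(x, ...) {
  cat(sprintf("Chamber experiment: %s (%d steps, %.0f-%.0f K, PPFD %g)\n",
              x$species_label, nrow(x$steps), min(x$steps$temp),
              max(x$steps$temp), x$ppfd))
  invisible(x)
}

#' Fit an Arrhenius temperature response to a chamber experiment
#'
#' Ordinary least squares of `ln(emission)` on `x = (1/303.15 - 1/T)/R`,
#' so the slope is the activation energy Ea (kJ mol^-1) and
#' `exp(intercept)` is the emission factor at 30 degrees C (EF30). Steps
#' above `t_max` are excluded (the exponential form degrades at high leaf
#' temperature); zero-emission steps are dropped with a warning.
#'
#' @param exp A [chamber_experiment()].
#' @param t_max Upper leaf-temperature bound for the fit, K
#'   (default 35 degrees C).
#' @param R Gas constant, kJ mol^-1 K^-1.
#' @return An object of class `arrhenius_fit`: list with `Ea` (kJ mol^-1),
#'   `EF30` (nmol m^-2 s^-1), `r_squared`, `n_points`, `n_excluded`,
#'   `t_range` (K), and the species label.
#' @export
fit_arrhenius <- function(exp, t_max = 308.15, R = GAS_CONSTANT_KJ) {
  stopifnot(inherits(exp, "chamber_experiment"))
  st <- exp$steps[exp$steps$temp <= t_max, , drop = FALSE]
  n_excluded <- nrow(exp$steps) - nrow(st)
  zero <- st$emission <= 0
  if (any(zero)) {
    warning(sprintf("%d step(s) with non-positive emission dropped",
                    sum(zero)))
    st <- st[!zero, , drop = FALSE]
  }
  if (nrow(st) < 2 || length(unique(st$temp)) < 2) {
    stop("fewer than 2 usable steps below t_max with positive emission")
  }
  x <- (1 / T_STANDARD_K - 1 / st$temp) / R
  fit <- stats::lm(log(st$emission) ~ x)
  ly <- log(st$emission)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1
        else max(0, min(1, 1 - sum(stats::residuals(fit)^2) / sst))
  structure(
    list(Ea = unname(stats::coef(fit)[2]),
         EF30 = unname(exp(stats::coef(fit)[1])),
         r_squared = r2,
         n_points = nrow(st),
         n_excluded = n_excluded,
         t_range = range(st$temp),
         species_label = exp$species_label),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius fit (%s): Ea = %.1f kJ/mol, EF30 = %.2f nmol/m2/s, R2 = %.3f (n = %d)\n",
    x$species_label, x$Ea, x$EF30, x$r_squared, x$n_points))
  invisible(x)
}

#' Q10 from measured temperature steps
#'
#' Ratio of the measured emission at the steps nearest 35 and 25 degrees C
#' (within `tol`), exponent-corrected to a 10 K bracket when the matched
#' step temperatures are not exactly 10 K apart.
#'
#' @param exp A [chamber_experiment()].
#' @param T1,T2 Bracket temperatures, K.
#' @param tol Step-matching tolerance, K.
#' @return Dimensionless Q10.
#' @export
q10_from_steps <- function(exp, T1 = 298.15, T2 = 308.15, tol = 0.5) {
  stopifnot(inherits(exp, "chamber_experiment"))
  pick <- function(target) {
    d <- abs(exp$steps$temp - target)
    i <- which.min(d)
    if (d[i] > tol) {
      stop(sprintf("no step within %g K of %g K", tol, target))
    }
    i
  }
  i1 <- pick(T1); i2 <- pick(T2)
  e1 <- exp$steps$emission[i1]; e2 <- exp$steps$emission[i2]
  if (e1 <= 0 || e2 <= 0) stop("non-positive emission at bracket step")
  dT <- exp$steps$temp[i2] - exp$steps$temp[i1]
  (e2 / e1)^(10 / dT)
}

#' Lag correlation of fitted parameters with temperature history
#'
#' For each lag k = 1..`max_lag` days, correlates the fitted activation
#' energy and EF30 across experiments with the mean air temperature of the
#' most recent k days, and reports the lag maximising |r| for each
#' response. This is the screen used to choose the acclimation window (the
#' 10-day mean).
#'
#' @param fits List of [fit_arrhenius()] results.
#' @param histories List of prior-daily-mean vectors (K, most recent
#'   first), one per fit, each of length >= `max_lag`.
#' @param max_lag Longest trailing window, days.
#' @param alpha Significance level for the t-test on Pearson r.
#' @return A list with `table` (data.frame: `lag_days`, `r_ea`, `p_ea`,
#'   `r_ef`, `p_ef`), `best_lag_ea`, `best_lag_ef`.
#' @export
history_correlation <- function(fits, histories, max_lag = 15,
                                alpha = 0.05) {
  if (length(fits) != length(histories)) {
    stop("fits and histories must have the same length")
  }
  if (length(fits) < 3) stop("need at least 3 experiments")
  short <- vapply(histories, length, 1L) < max_lag
  if (any(short)) {
    stop(sprintf("each history needs >= %d daily means", max_lag))
  }
  ea <- vapply(fits, function(f) f$Ea, 1)
  ef <- vapply(fits, function(f) f$EF30, 1)
  one_lag <- function(k, y) {
    pred <- vapply(histories, function(h) mean(h[seq_len(k)]), 1)
    if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(pred, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  tab <- data.frame(lag_days = seq_len(max_lag))
  rea <- t(vapply(tab$lag_days, one_lag, c(r = 1, p = 1), y = ea))
  ref <- t(vapply(tab$lag_days, one_lag, c(r = 1, p = 1), y = ef))
  tab$r_ea <- rea[, "r"]; tab$p_ea <- rea[, "p"]
  tab$r_ef <- ref[, "r"]; tab$p_ef <- ref[, "p"]
  best <- function(r, p) {
    if (all(is.na(r))) return(NA_integer_)
    i <- which.max(abs(r))
    structure(tab$lag_days[i], significant = isTRUE(p[i] < alpha))
  }
  list(table = tab,
       best_lag_ea = best(tab$r_ea, tab$p_ea),
       best_lag_ef = best(tab$r_ef, tab$p_ef),
       alpha = alpha)
}

#' Fit the sedge acclimation functions to per-experiment Arrhenius fits
#'
#' Recovers the coefficients of the activation-energy acclimation
#' `Ea = base + C_amp exp(C_rate (288.15 - T240))` by Levenberg-Marquardt
#' nonlinear least squares (base held fixed), and the emission-factor
#' acclimation rate by OLS of `ln(EF30)` on `T240 - 288.15` (EF normalised
#' at the reference 10-day mean).
#'
#' @param pairs_ea data.frame with columns `T240` (K) and `Ea` (kJ mol^-1).
#' @param pairs_ef data.frame with columns `T240` (K) and `EF30`
#'   (nmol m^-2 s^-1, positive).
#' @param base Fixed activation-energy asymptote, kJ mol^-1.
#' @param T240_ref Reference 10-day mean, K.
#' @return A [sedge_response_params()] object with fitted `C_amp`,
#'   `C_rate`, `EF_rate`; attributes `ea_resid_norm`, `ef_resid_norm`, and
#'   `EF30_ref` (fitted EF30 at the reference T240).
#' @export
fit_acclimation <- function(pairs_ea, pairs_ef, base = 95,
                            T240_ref = 288.15) {
  for (nm in c("T240", "Ea")) {
    if (!nm %in% names(pairs_ea)) stop("pairs_ea needs columns T240, Ea")
  }
  for (nm in c("T240", "EF30")) {
    if (!nm %in% names(pairs_ef)) stop("pairs_ef needs columns T240, EF30")
  }
  if (nrow(pairs_ea) < 3 || nrow(pairs_ef) < 3) {
    stop("need at least 3 (T240, value) pairs for each response")
  }
  if (diff(range(pairs_ea$T240)) < 5 || diff(range(pairs_ef$T240)) < 5) {
    stop("T240 must span at least 5 K for identifiability")
  }
  if (any(pairs_ef$EF30 <= 0)) stop("EF30 values must be positive")

  excess <- pairs_ea$Ea - base
  amp0 <- max(max(excess), 1e-2)
  df <- data.frame(T240 = pairs_ea$T240, Ea = pairs_ea$Ea)
  fit <- try(minpack.lm::nlsLM(
    Ea ~ base + amp * exp(rate * (T240_ref - T240)),
    data = df,
    start = list(amp = amp0, rate = 0.5),
    lower = c(amp = 1e-8, rate = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("acclimation fit did not converge: ",
         attr(fit, "condition")$message)
  }
  cf <- stats::coef(fit)
  if (cf[["amp"]] <= 0) stop("negative fitted amplitude")

  x <- pairs_ef$T240 - T240_ref
  lf <- stats::lm(log(pairs_ef$EF30) ~ x)
  ef_rate <- unname(stats::coef(lf)[2])
  if (ef_rate <= 0) {
    stop("fitted EF_rate is non-positive; data do not show the expected ",
         "capacity increase with T240")
  }
  out <- sedge_response_params(C_base = base, C_amp = cf[["amp"]],
                               C_rate = cf[["rate"]], T240_ref = T240_ref,
                               EF_rate = ef_rate)
  attr(out, "ea_resid_norm") <- sqrt(sum(stats::residuals(fit)^2))
  attr(out, "ef_resid_norm") <- sqrt(sum(stats::residuals(lf)^2))
  attr(out, "EF30_ref") <- unname(exp(stats::coef(lf)[1]))
  out
}
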