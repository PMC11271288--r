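#' Configuration for the synthetic-data generators
#'
#' Bundles a seed, the true response parameters, and the statistical shape
#' of the generated records. Defaults emulate the study regime: Arctic
#' summer chamber experiments on sedges with 10-day mean temperatures
#' between 10 and 20 degrees C, a leaf-level sedge emission factor of
#' 12.0 nmol m^-2 s^-1 (willow 6.5), 5% multiplicative chamber noise, and
#' half-hourly site series with additive noise at 10% of the mean flux.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_experiments Number of chamber experiments.
#' @param T240_range Range (K) from which each experiment's 10-day mean
#'   temperature is drawn.
#' @param chamber_noise_sd Lognormal sigma of the multiplicative emission
#'   noise.
#' @param site_noise_frac Additive Gaussian noise sd as a fraction of the
#'   mean flux.
#' @param sedge_params,willow_params True acclimation parameters.
#' @param leaf_ef_sedge,leaf_ef_willow True leaf-level emission factors,
#'   nmol m^-2 s^-1.
#' @param cf_sedge,cf_shrub True cover fractions.
#' @param t_mean Site mean air temperature, K.
#' @param diurnal_amp,seasonal_amp Diurnal and seasonal temperature
#'   amplitudes, K.
#' @param ar1_coef,ar1_sd AR(1) coefficient and innovation sd (K) of the
#'   daily synoptic component.
#' @param latitude Site latitude, degrees N (shapes the PPFD curve).
#' @param ppfd_max Clear-sky PPFD at unit solar elevation,
#'   umol m^-2 s^-1.
#' @param start Start date of site series (`Date` or string).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_experiments = 20,
                             T240_range = c(283.15, 293.15),
                             chamber_noise_sd = 0.05,
                             site_noise_frac = 0.10,
                             sedge_params = sedge_response_params(),
                             willow_params = willow_capacity_params(),
                             leaf_ef_sedge = 12.0, leaf_ef_willow = 6.5,
                             cf_sedge = 0.25, cf_shrub = 0.10,
                             t_mean = 284.15, diurnal_amp = 4,
                             seasonal_amp = 3, ar1_coef = 0.8,
                             ar1_sd = 1.5, latitude = 68,
                             ppfd_max = 1800,
                             start = "2021-06-01") {
  if (chamber_noise_sd < 0 || site_noise_frac < 0) {
    stop("noise sds must be >= 0")
  }
  if (diff(T240_range) < 0) stop("T240_range must be increasing")
  structure(
    list(seed = as.integer(seed), n_experiments = n_experiments,
         T240_range = T240_range, chamber_noise_sd = chamber_noise_sd,
         site_noise_frac = site_noise_frac, sedge_params = sedge_params,
         willow_params = willow_params, leaf_ef_sedge = leaf_ef_sedge,
         leaf_ef_willow = leaf_ef_willow, cf_sedge = cf_sedge,
         cf_shrub = cf_shrub, t_mean = t_mean, diurnal_amp = diurnal_amp,
         seasonal_amp = seasonal_amp, ar1_coef = ar1_coef,
         ar1_sd = ar1_sd, latitude = latitude, ppfd_max = ppfd_max,
         start = as.Date(start)),
    class = "synthetic_config"
  )
}

#' Generate synthetic chamber temperature-ramp experiments
#'
#' Each experiment draws a 10-day mean temperature T240 from the configured
#' range, ramps leaf temperature 15 to 40 degrees C in 5 K steps, and sets
#' the emission at each step to the sedge model
#' `EF30 * e_opt_sg(T240) * exp(c_sg(T240)/R (1/303.15 - 1/T))` times
#' lognormal noise. The 15 preceding daily means are generated so that the
#' most recent 10 average exactly to the drawn T240.
#'
#' @param cfg A [synthetic_config()].
#' @param step_temps_c Ramp temperatures, degrees C.
#' @return List of [chamber_experiment()] objects; attribute `truth` holds
#'   the per-experiment T240 and noise-free parameters.
#' @export
gen_chamber <- function(cfg = synthetic_config(),
                        step_temps_c = seq(15, 40, by = 5)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  steps_k <- celsius_to_kelvin(step_temps_c)
  p <- cfg$sedge_params
  out <- vector("list", cfg$n_experiments)
  truth <- data.frame(experiment = seq_len(cfg$n_experiments),
                      T240 = NA_real_, Ea = NA_real_, EF30 = NA_real_)
  for (i in seq_len(cfg$n_experiments)) {
    T240 <- stats::runif(1, cfg$T240_range[1], cfg$T240_range[2])
    ea <- c_sg(T240, p)
    ef30 <- cfg$leaf_ef_sedge * e_opt_sg(T240, p)
    emission <- ef30 * exp(ea / GAS_CONSTANT_KJ *
                             (1 / p$T_std - 1 / steps_k))
    if (cfg$chamber_noise_sd > 0) {
      emission <- emission * stats::rlnorm(length(emission), 0,
                                           cfg$chamber_noise_sd)
    }
    # 15 prior daily means; recent 10 recentred to average exactly T240
    days <- T240 + stats::rnorm(15, 0, 1.0)
    days[1:10] <- days[1:10] - mean(days[1:10]) + T240
    out[[i]] <- chamber_experiment(
      species_label = sprintf("synthetic_sedge_%02d", i),
      step_temp = steps_k, emission_rate = emission,
      ppfd = 1000, prior_daily_means = days)
    truth$T240[i] <- T240
    truth$Ea[i] <- ea
    truth$EF30[i] <- ef30
  }
  attr(out, "truth") <- truth
  out
}

# Solar-elevation-shaped PPFD for a given latitude and time of year.
.ppfd_curve <- function(timestamps, latitude, ppfd_max) {
  doy <- as.numeric(format(timestamps, "%j"))
  hour <- as.numeric(format(timestamps, "%H")) +
    as.numeric(format(timestamps, "%M")) / 60
  decl <- 23.45 * pi / 180 * sin(2 * pi * (doy + 284) / 365)
  lat <- latitude * pi / 180
  ha <- (hour - 12) * pi / 12
  sin_elev <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  ppfd_max * pmax(sin_elev, 0)
}

#' Generate a synthetic half-hourly site met/flux record
#'
#' Air temperature is seasonal + diurnal sinusoids plus a daily AR(1)
#' synoptic component (linearly interpolated to half-hours); PPFD follows
#' a solar-elevation curve for the configured latitude; LAI ramps with the
#' season. Acclimation means come from [trailing_means()], the true flux
#' from [model_flux()] with the configured sedge/shrub PFTs and cover
#' fractions, and additive Gaussian noise is applied. An optional heatwave
#' raises air temperature by `heatwave_amp` K for `heatwave_days` days
#' starting mid-record.
#'
#' @param cfg A [synthetic_config()].
#' @param n_days Record length, days (>= 20 so T240 is populated).
#' @param heatwave_amp Heatwave amplitude, K (0 disables).
#' @param heatwave_days Heatwave length, days.
#' @return List with `series` (data.frame: `timestamp`, `t_air`, `ppfd`,
#'   `lai`, `T24`, `T240`, `flux_true`, `flux`), `pfts` (true PFT list),
#'   and `truth` (true cover fractions and noise sd).
#' @export
gen_site <- function(cfg = synthetic_config(), n_days = 60,
                     heatwave_amp = 0, heatwave_days = 5) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (n_days < 20) stop("n_days must be >= 20 to populate T240")
  set.seed(cfg$seed + 1L)
  n <- n_days * 48
  ts <- seq(as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC"),
            by = 1800, length.out = n)
  frac_day <- (seq_len(n) - 1) / 48
  seasonal <- cfg$seasonal_amp * sin(2 * pi * (frac_day - n_days / 4) /
                                       (2 * n_days))
  diurnal <- cfg$diurnal_amp * sin(2 * pi * (frac_day %% 1) - pi / 2)
  syn_daily <- as.numeric(stats::arima.sim(
    list(ar = cfg$ar1_coef), n = n_days, sd = cfg$ar1_sd))
  synoptic <- stats::approx(seq(0, n_days - 1), syn_daily,
                            xout = frac_day, rule = 2)$y
  t_air <- cfg$t_mean + seasonal + diurnal + synoptic
  if (heatwave_amp > 0) {
    hw0 <- floor(n_days / 2)
    inhw <- frac_day >= hw0 & frac_day < hw0 + heatwave_days
    t_air[inhw] <- t_air[inhw] + heatwave_amp
  }
  ppfd <- .ppfd_curve(ts, cfg$latitude, cfg$ppfd_max)
  lai <- 0.5 + 0.5 * frac_day / n_days      # green-up over the record
  tm <- trailing_means(ts, t_air)
  series <- data.frame(timestamp = ts, t_air = t_air, ppfd = ppfd,
                       lai = lai, T24 = tm$T24, T240 = tm$T240)
  pfts <- list(
    site_pft("sedge", cfg$leaf_ef_sedge, "sedge",
             cover_fraction = cfg$cf_sedge),
    site_pft("shrub", cfg$leaf_ef_willow, "willow",
             cover_fraction = cfg$cf_shrub))
  flux_true <- model_flux(series, pfts,
                          sedge_params = cfg$sedge_params,
                          willow_params = cfg$willow_params)
  noise_sd <- cfg$site_noise_frac * mean(flux_true, na.rm = TRUE)
  series$flux_true <- flux_true
  series$flux <- flux_true +
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  list(series = series, pfts = pfts,
       truth = list(cf = c(sedge = cfg$cf_sedge, shrub = cfg$cf_shrub),
                    noise_sd = noise_sd))
}
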