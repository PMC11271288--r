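#' Universal gas constant used throughout the package
#'
#' Value in kJ mol^-1 K^-1, the unit convention of the MEGAN temperature
#' response equations (activation energies in kJ mol^-1).
#' @export
GAS_CONSTANT_KJ <- 0.008314

#' Standard-condition leaf temperature (30 degrees C, in K)
#'
#' Emission factors are defined at this leaf temperature and a PPFD of
#' 1000 umol m^-2 s^-1.
#' @export
T_STANDARD_K <- 303.15

#' Molar mass of isoprene (g mol^-1)
#' @export
ISOPRENE_MOLAR_MASS <- 68.12

# Physical plausibility window for any temperature entering a response curve.
.T_MIN <- 200
.T_MAX <- 330

#' Parameters of the default MEGANv2.1 isoprene temperature response
#'
#' Holds the coefficients of the short-term activity factor gamma_T and of
#' the long-term (acclimation) expressions for the optimum temperature
#' `Topt = Topt_base + Topt_slope * (T240 - Tref)` and optimum activity
#' `Eopt = Eopt_scale * exp(Eopt_rate24 * (T24 - Tref)) *
#' exp(Eopt_rate240 * (T240 - Tref))`.
#'
#' @param CT1 Activation energy, kJ mol^-1.
#' @param CT2 Deactivation energy, kJ mol^-1; must exceed `CT1`.
#' @param R Gas constant, kJ mol^-1 K^-1.
#' @param Topt_base,Topt_slope Optimum-temperature acclimation intercept (K)
#'   and slope (K per K of `T240`).
#' @param Tref Reference acclimation temperature, K.
#' @param Eopt_scale Optimum activity at reference acclimation
#'   (dimensionless).
#' @param Eopt_rate24,Eopt_rate240 Acclimation rates of `Eopt` with `T24` and
#'   `T240`, K^-1.
#' @return An object of class `default_response_params`.
#' @examples
#' p <- default_response_params()
#' t_opt(297.15, p)   # 313 K at reference acclimation
#' @export
default_response_params <- function(CT1 = 95, CT2 = 230, R = GAS_CONSTANT_KJ,
                                    Topt_base = 313, Topt_slope = 0.6,
                                    Tref = 297.15, Eopt_scale = 2,
                                    Eopt_rate24 = 0.05, Eopt_rate240 = 0.05) {
  stopifnot(is.numeric(CT1), is.numeric(CT2), is.numeric(R))
  if (!(CT2 > CT1 && CT1 > 0)) {
    stop("require CT2 > CT1 > 0 (deactivation above activation energy)")
  }
  if (R <= 0) stop("gas constant R must be positive")
  structure(
    list(CT1 = CT1, CT2 = CT2, R = R,
         Topt_base = Topt_base, Topt_slope = Topt_slope, Tref = Tref,
         Eopt_scale = Eopt_scale, Eopt_rate24 = Eopt_rate24,
         Eopt_rate240 = Eopt_rate240),
    class = "default_response_params"
  )
}

#' Parameters of the sedge temperature response and its acclimation
#'
#' The sedge short-term response is a pure Arrhenius exponential whose
#' activation energy `C_sg = C_base + C_amp * exp(C_rate * (T240_ref - T240))`
#' falls towards the default MEGAN activation energy as the 10-day mean
#' temperature rises, while the emission-factor multiplier
#' `exp(EF_rate * (T240 - T240_ref))` rises — the inverse
#' sensitivity/capacity relationship observed in sedges.
#'
#' @param C_base Warm-acclimation asymptote of the activation energy,
#'   kJ mol^-1 (the default MEGAN CT1).
#' @param C_amp Amplitude of the cold-acclimation increase, kJ mol^-1.
#' @param C_rate Acclimation rate of the activation energy, K^-1.
#' @param T240_ref Reference 10-day mean temperature, K.
#' @param EF_rate Acclimation rate of the emission factor, K^-1.
#' @param T_std Standard leaf temperature at which the response equals the
#'   emission-factor multiplier, K.
#' @return An object of class `sedge_response_params`.
#' @export
sedge_response_params <- function(C_base = 95, C_amp = 9.5, C_rate = 0.53,
                                  T240_ref = 288.15, EF_rate = 0.12,
                                  T_std = T_STANDARD_K) {
  if (C_base <= 0 || C_amp <= 0) stop("C_base and C_amp must be positive")
  if (C_rate <= 0 || EF_rate <= 0) stop("C_rate and EF_rate must be positive")
  structure(
    list(C_base = C_base, C_amp = C_amp, C_rate = C_rate,
         T240_ref = T240_ref, EF_rate = EF_rate, T_std = T_std),
    class = "sedge_response_params"
  )
}

#' Parameters of the willow acclimating emission capacity
#'
#' The boreal broadleaf deciduous shrub (willow) keeps the default MEGAN
#' short-term curve shape but its optimum activity is replaced by
#' `scale * exp(rate * (T24 - T24_ref))`, an emission capacity that tracks
#' the previous-day mean air temperature.
#'
#' @param scale Capacity at the reference previous-day mean (dimensionless).
#' @param rate Acclimation rate, K^-1.
#' @param T24_ref Reference previous-day mean temperature, K.
#' @return An object of class `willow_capacity_params`.
#' @export
willow_capacity_params <- function(scale = 7.9, rate = 0.22,
                                   T24_ref = 297.15) {
  if (scale <= 0) stop("capacity scale must be positive")
  structure(
    list(scale = scale, rate = rate, T24_ref = T24_ref),
    class = "willow_capacity_params"
  )
}

#' @export
print.default_response_params <- function(x, ...) {
  cat("Default MEGANv2.1 temperature-response parameters\n")
  cat(sprintf("  CT1 = %g, CT2 = %g kJ/mol; R = %g kJ/mol/K\n",
              x$CT1, x$CT2, x$R))
  cat(sprintf("  Topt = %g + %g (T240 - %g) K; Eopt = %g e^{%g dT24} e^{%g dT240}\n",
              x$Topt_base, x$Topt_slope, x$Tref,
              x$Eopt_scale, x$Eopt_rate24, x$Eopt_rate240))
  invisible(x)
}

#' @export
print.sedge_response_params <- function(x, ...) {
  cat("Sedge temperature-response parameters\n")
  cat(sprintf("  C_sg = %g + %g exp(%g (%g - T240)) kJ/mol\n",
              x$C_base, x$C_amp, x$C_rate, x$T240_ref))
  cat(sprintf("  EF multiplier = exp(%g (T240 - %g))\n", x$EF_rate, x$T240_ref))
  invisible(x)
}

#' @export
print.willow_capacity_params <- function(x, ...) {
  cat("Willow emission-capacity parameters\n")
  cat(sprintf("  Eopt = %g exp(%g (T24 - %g))\n", x$scale, x$rate, x$T24_ref))
  invisible(x)
}

# Shared temperature guard: finite and physically plausible, NA allowed when
# `na_ok` (acclimation spin-up produces NA).
.check_temperature <- function(x, what, na_ok = FALSE) {
  bad <- if (na_ok) !is.na(x) & (!is.finite(x) | x <= .T_MIN | x >= .T_MAX)
         else !is.finite(x) | x <= .T_MIN | x >= .T_MAX
  if (any(bad)) {
    stop(sprintf(
      "%s outside the physically plausible range (%g, %g) K: first offender %s",
      what, .T_MIN, .T_MAX, format(x[bad][1])))
  }
  invisible(x)
}

#' Convert Celsius to Kelvin
#' @param x Temperature(s) in degrees Celsius.
#' @return Temperature(s) in Kelvin.
#' @export
celsius_to_kelvin <- function(x) x + 273.15
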