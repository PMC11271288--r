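#' Sedge activation energy as a function of 10-day mean temperature
#'
#' `C_sg = 95 + 9.5 exp(0.53 (288.15 - T240))` kJ mol^-1: cold-acclimated
#' sedges have a very steep temperature response; as the 10-day mean warms
#' the activation energy decays to the default MEGAN value of 95 kJ mol^-1.
#'
#' @param T240 Mean air temperature of the previous 240 h, K.
#' @param params A [sedge_response_params()] object.
#' @return Activation energy, kJ mol^-1; always > `C_base`, strictly
#'   decreasing in `T240`.
#' @examples
#' c_sg(288.15)  # 104.5
#' @export
c_sg <- function(T240, params = sedge_response_params()) {
  .check_temperature(T240, "T240", na_ok = TRUE)
  params$C_base + params$C_amp * exp(params$C_rate * (params$T240_ref - T240))
}

#' Sedge emission-factor acclimation multiplier
#'
#' `exp(0.12 (T240 - 288.15))`: the emission capacity of sedges rises with
#' the 10-day mean temperature, the counterpart of the falling activation
#' energy in [c_sg()].
#'
#' @inheritParams c_sg
#' @return Dimensionless multiplier, strictly increasing in `T240`.
#' @export
e_opt_sg <- function(T240, params = sedge_response_params()) {
  .check_temperature(T240, "T240", na_ok = TRUE)
  exp(params$EF_rate * (T240 - params$T240_ref))
}

#' Sedge short-term temperature activity factor
#'
#' A pure Arrhenius exponential with acclimating activation energy and
#' capacity:
#' `gamma = e_opt_sg(T240) * exp(c_sg(T240)/R * (1/303.15 - 1/T))`.
#' There is no high-temperature deactivation term; the curve keeps rising
#' with leaf temperature. Above 40 degrees C the exponential form is known
#' to overstate emission, so a warning is emitted for leaf temperatures
#' beyond 313.15 K.
#'
#' @param T Leaf temperature, K (vectorised).
#' @param T240 Mean air temperature of the previous 240 h, K.
#' @param params A [sedge_response_params()] object.
#' @param R Gas constant, kJ mol^-1 K^-1.
#' @return Dimensionless activity factor, strictly positive and strictly
#'   increasing in `T`.
#' @export
gamma_t_sedge <- function(T, T240 = 288.15,
                          params = sedge_response_params(),
                          R = GAS_CONSTANT_KJ) {
  .check_temperature(T, "leaf temperature")
  if (any(T > 313.15, na.rm = TRUE)) {
    warning("leaf temperature above 313.15 K: the exponential sedge ",
            "response is not validated beyond 40 degrees C")
  }
  e_opt_sg(T240, params) *
    exp(c_sg(T240, params) / R * (1 / params$T_std - 1 / T))
}

#' Willow acclimating emission capacity
#'
#' `Eopt = 7.9 exp(0.22 (T24 - 297.15))`: the optimum activity of the
#' boreal broadleaf deciduous shrub response tracks the previous-day mean
#' air temperature.
#'
#' @param T24 Mean air temperature of the previous 24 h, K.
#' @param params A [willow_capacity_params()] object.
#' @return Dimensionless capacity, strictly positive.
#' @export
e_opt_willow <- function(T24, params = willow_capacity_params()) {
  .check_temperature(T24, "T24", na_ok = TRUE)
  params$scale * exp(params$rate * (T24 - params$T24_ref))
}

#' Willow short-term temperature activity factor
#'
#' The default MEGAN curve shape (activation/deactivation, optimum from
#' [t_opt()]) with its optimum activity replaced by the acclimating
#' capacity [e_opt_willow()].
#'
#' @param T Leaf temperature, K (vectorised).
#' @param T24,T240 Acclimation temperatures, K.
#' @param default_params A [default_response_params()] object supplying the
#'   curve shape (CT1, CT2, Topt acclimation).
#' @param willow_params A [willow_capacity_params()] object.
#' @return Dimensionless activity factor; equals `e_opt_willow(T24)` at the
#'   optimum temperature.
#' @export
gamma_t_willow <- function(T, T24 = 297.15, T240 = 297.15,
                           default_params = default_response_params(),
                           willow_params = willow_capacity_params()) {
  .check_temperature(T, "leaf temperature")
  .check_temperature(T24, "T24", na_ok = TRUE)
  .check_temperature(T240, "T240", na_ok = TRUE)
  p <- default_params
  Topt <- p$Topt_base + p$Topt_slope * (T240 - p$Tref)
  Eopt <- e_opt_willow(T24, willow_params)
  x <- 1 / Topt - 1 / T
  denom <- p$CT2 - p$CT1 * (1 - exp(p$CT2 / p$R * x))
  if (any(denom <= 0, na.rm = TRUE)) {
    stop("internal error: non-positive denominator in gamma_t_willow")
  }
  Eopt * p$CT2 * exp(p$CT1 / p$R * x) / denom
}

# Dispatch a temperature response by PFT response kind.
# Returns a vector of gamma_T for leaf temperature T and acclimation T24/T240.
.gamma_t_by_kind <- function(kind, T, T24, T240,
                             default_params = default_response_params(),
                             sedge_params = sedge_response_params(),
                             willow_params = willow_capacity_params()) {
  switch(kind,
    sedge = suppressWarnings(
      gamma_t_sedge(T, T240, params = sedge_params)),
    willow = gamma_t_willow(T, T24, T240, default_params, willow_params),
    default = gamma_t_default(T, T24, T240, default_params),
    stop(sprintf("unknown response kind '%s' (use sedge/willow/default)",
                 kind))
  )
}
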