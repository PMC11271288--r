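#' Optimum temperature of the default isoprene response
#'
#' `Topt = 313 + 0.6 (T240 - 297.15)`: the temperature of peak short-term
#' activity shifts with the 10-day mean air temperature.
#'
#' @param T240 Mean air temperature of the previous 240 h, K.
#' @param params A [default_response_params()] object.
#' @return Optimum temperature, K (vectorised over `T240`).
#' @export
t_opt <- function(T240, params = default_response_params()) {
  .check_temperature(T240, "T240")
  params$Topt_base + params$Topt_slope * (T240 - params$Tref)
}

#' Optimum activity of the default isoprene response
#'
#' `Eopt = 2 exp(0.05 (T24 - 297.15)) exp(0.05 (T240 - 297.15))`: the peak
#' value of the short-term curve grows exponentially with both the 1-day and
#' 10-day mean air temperatures.
#'
#' @param T24,T240 Mean air temperatures of the previous 24 h and 240 h, K.
#' @inheritParams t_opt
#' @return Dimensionless optimum activity, strictly positive.
#' @export
e_opt_default <- function(T24, T240, params = default_response_params()) {
  .check_temperature(T24, "T24")
  .check_temperature(T240, "T240")
  params$Eopt_scale *
    exp(params$Eopt_rate24 * (T24 - params$Tref)) *
    exp(params$Eopt_rate240 * (T240 - params$Tref))
}

#' Default MEGANv2.1 short-term temperature activity factor
#'
#' The dimensionless multiplier gamma_T applied to the emission factor:
#' an activation/deactivation form that peaks at [t_opt()] with value
#' [e_opt_default()], rising with activation energy CT1 below the optimum
#' and collapsing with deactivation energy CT2 above it.
#'
#' @param T Leaf temperature, K (vectorised).
#' @param T24,T240 Acclimation temperatures, K (scalar or same length as
#'   `T`); `NA` values (acclimation spin-up) propagate to `NA` output.
#' @inheritParams t_opt
#' @return Dimensionless activity factor, positive where inputs are
#'   non-missing.
#' @examples
#' gamma_t_default(303.15, 297.15, 297.15)  # ~1 at standard conditions
#' @export
gamma_t_default <- function(T, T24 = 297.15, T240 = 297.15,
                            params = default_response_params()) {
  .check_temperature(T, "leaf temperature")
  .check_temperature(T24, "T24", na_ok = TRUE)
  .check_temperature(T240, "T240", na_ok = TRUE)
  Topt <- params$Topt_base + params$Topt_slope * (T240 - params$Tref)
  Eopt <- params$Eopt_scale *
    exp(params$Eopt_rate24 * (T24 - params$Tref)) *
    exp(params$Eopt_rate240 * (T240 - params$Tref))
  x <- 1 / Topt - 1 / T
  denom <- params$CT2 - params$CT1 * (1 - exp(params$CT2 / params$R * x))
  # For CT2 > CT1 > 0 the denominator is CT2 at the optimum and grows as
  # exp() > 1 below it / stays above CT2 - CT1 above it; <= 0 would mean a
  # broken parameterisation.
  if (any(denom <= 0, na.rm = TRUE)) {
    stop("internal error: non-positive denominator in gamma_t_default")
  }
  Eopt * params$CT2 * exp(params$CT1 / params$R * x) / denom
}

#' Trailing 24-h and 240-h mean air temperatures
#'
#' Computes, for every timestamp of a regularly sampled series, the
#' arithmetic mean of the strictly preceding samples inside trailing windows
#' of 24 h and 240 h (left-open, right-closed at the previous sample: the
#' sample at time t does not contribute to its own means). Timestamps with
#' less than 240 h of history are flagged missing (`NA`) rather than given
#' shortened-window means.
#'
#' @param timestamps `POSIXct` vector, regularly sampled, increasing.
#' @param t_air Air temperature at each timestamp, K.
#' @param gap_tol Relative tolerance on sampling-interval jitter; any gap
#'   differing from the modal interval by more than this fraction is an
#'   error naming the gap.
#' @return A `data.frame` with columns `timestamp`, `T24`, `T240`.
#' @examples
#' ts <- seq(as.POSIXct("2021-06-01", tz = "UTC"), by = 1800,
#'           length.out = 600)
#' tm <- trailing_means(ts, rep(290, 600))
#' tail(tm$T240, 1)  # 290 after spin-up
#' @export
trailing_means <- function(timestamps, t_air, gap_tol = 1e-3) {
  if (length(timestamps) != length(t_air)) {
    stop("timestamps and t_air must have the same length")
  }
  n <- length(t_air)
  if (n < 2) stop("need at least two samples")
  .check_temperature(t_air, "air temperature")
  dt <- as.numeric(difftime(timestamps[-1], timestamps[-n], units = "secs"))
  step <- stats::median(dt)
  if (step <= 0) stop("timestamps must be strictly increasing")
  off <- which(abs(dt - step) > gap_tol * step)
  if (length(off)) {
    stop(sprintf(
      "irregular sampling: gap of %g s after %s (expected %g s)",
      dt[off[1]], format(timestamps[off[1]]), step))
  }
  n24 <- round(24 * 3600 / step)
  n240 <- round(240 * 3600 / step)
  if (n24 < 1) stop("sampling interval exceeds 24 h")
  cs <- c(0, cumsum(t_air))
  win_mean <- function(k) {
    out <- rep(NA_real_, n)
    if (n > k) {
      i <- (k + 1):n
      out[i] <- (cs[i] - cs[i - k]) / k
    }
    out
  }
  data.frame(timestamp = timestamps, T24 = win_mean(n24),
             T240 = win_mean(n240))
}

#' Q10 temperature coefficient of an emission response curve
#'
#' Factor by which emission changes for a 10 K rise in leaf temperature,
#' computed from the curve values at two temperatures and exponent-corrected
#' when the bracket is not exactly 10 K:
#' `(curve(T2)/curve(T1))^(10/(T2 - T1))`. The default bracket is
#' 25-35 degrees C.
#'
#' @param curve Function mapping leaf temperature (K) to emission or
#'   activity (positive).
#' @param T1,T2 Bracket temperatures, K, `T2 > T1`.
#' @return Dimensionless Q10.
#' @examples
#' q10(function(T) exp(104.5 / 0.008314 * (1 / 303.15 - 1 / T)))  # ~3.93
#' @export
q10 <- function(curve, T1 = 298.15, T2 = 308.15) {
  if (!is.function(curve)) stop("curve must be a function of temperature")
  if (T2 <= T1) stop("require T2 > T1")
  v1 <- curve(T1)
  v2 <- curve(T2)
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0) {
    stop("curve must be positive and finite at both bracket temperatures")
  }
  (v2 / v1)^(10 / (T2 - T1))
}
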