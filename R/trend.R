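#' Annual isoprene emission totals from a met record
#'
#' Runs the site flux model over a multi-year half-hourly met record and
#' integrates each complete calendar year (trapezoidal rule over the
#' half-hour steps), converting to mass per area with the isoprene molar
#' mass. Partial years are dropped with a warning; the `model` switch
#' selects the default MEGAN responses for every PFT or each PFT's own
#' (updated) response kind.
#'
#' @param series data.frame with `timestamp` (POSIXct), `t_air` (K),
#'   `lai`; `T24`/`T240` computed if absent.
#' @param pfts List of [site_pft()] objects with cover fractions.
#' @param model `"updated"` (per-PFT response kinds) or `"default"` (all
#'   PFTs on the default MEGAN response).
#' @inheritParams model_flux
#' @return data.frame with `year`, `emission` (mg m^-2 yr^-1),
#'   `mean_t_air` (K).
#' @export
annual_emissions <- function(series, pfts, model = c("updated", "default"),
                             g_others = gamma_others(),
                             sedge_params = sedge_response_params(),
                             willow_params = willow_capacity_params(),
                             default_params = default_response_params()) {
  model <- match.arg(model)
  if (inherits(pfts, "site_pft")) pfts <- list(pfts)
  if (!all(c("T24", "T240") %in% names(series))) {
    tm <- trailing_means(series$timestamp, series$t_air)
    series$T24 <- tm$T24
    series$T240 <- tm$T240
  }
  if (model == "default") {
    pfts <- lapply(pfts, function(p) { p$response <- "default"; p })
  }
  flux <- model_flux(series, pfts, g_others, sedge_params, willow_params,
                     default_params)
  ok <- !is.na(flux)
  yr <- as.integer(format(series$timestamp, "%Y"))
  dt <- as.numeric(difftime(series$timestamp[2], series$timestamp[1],
                            units = "secs"))
  # a complete year holds every half-hour slot except acclimation spin-up,
  # tolerated only in the record's first 10 days
  out <- lapply(sort(unique(yr)), function(y) {
    i <- which(yr == y & ok)
    if (length(i) < 2) return(NULL)
    hours_present <- length(which(yr == y)) * dt / 3600
    year_hours <- (as.numeric(as.POSIXct(sprintf("%d-01-01", y + 1),
                                         tz = "UTC")) -
                   as.numeric(as.POSIXct(sprintf("%d-01-01", y),
                                         tz = "UTC"))) / 3600
    if (hours_present < year_hours - 1e-6) {
      warning(sprintf("partial year %d dropped (%.0f of %.0f h)", y,
                      hours_present, year_hours))
      return(NULL)
    }
    f <- flux[i]
    # trapezoid over nmol m^-2 s^-1 -> nmol m^-2, then to mg m^-2
    nmol <- sum((f[-1] + f[-length(f)]) / 2) * dt
    data.frame(year = y,
               emission = nmol * ISOPRENE_MOLAR_MASS * 1e-6,
               mean_t_air = mean(series$t_air[yr == y]))
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) stop("no complete years in series")
  out
}

# Exact null distribution of the Mann-Kendall S for tie-free series of
# length n: S = n(n-1)/2 - 2*inversions; inversion counts follow the
# Mahonian numbers, built by polynomial convolution.
.mk_exact_p <- function(s_obs, n) {
  counts <- 1
  for (k in 2:n) {
    new <- numeric(length(counts) + k - 1)
    for (j in 0:(k - 1)) {
      idx <- seq_along(counts) + j
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  m <- n * (n - 1) / 2
  s_vals <- m - 2 * (seq_along(counts) - 1)
  sum(counts[abs(s_vals) >= abs(s_obs)]) / sum(counts)
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotonic-trend test: `S` is the sum of `sign(x_j - x_i)`
#' over all pairs `i < j`; `tau` is the tie-corrected (tau-b) rank
#' correlation with time. For tie-free series with `n <= 10` the p-value is
#' exact (full null distribution of S); otherwise it uses the normal
#' approximation with tie-adjusted variance and continuity correction.
#'
#' @param x Ordered numeric series, length >= 4.
#' @return List with `S`, `tau`, `p_value`, `var_S`, `n`, `method`.
#' @examples
#' mann_kendall(1:10)  # S = 45, tau = 1
#' @export
mann_kendall <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("need at least 4 values")
  if (any(!is.finite(x))) stop("series must be finite")
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])
  ties <- table(x)
  ties <- ties[ties > 1]
  m <- n * (n - 1) / 2
  denom <- sqrt(m - sum(ties * (ties - 1) / 2)) * sqrt(m)
  tau <- if (denom == 0) 0 else S / denom
  var_S <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (length(ties) == 0 && n <= 10) {
    p <- .mk_exact_p(S, n)
    method <- "exact"
  } else if (var_S == 0) {
    p <- 1
    method <- "degenerate"
  } else {
    z <- (S - sign(S)) / sqrt(var_S)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(S = as.integer(S), tau = tau, p_value = min(p, 1), var_S = var_S,
       n = n, method = method)
}

#' Ordinary least-squares linear trend of an annual series
#'
#' @param series data.frame with columns `year` and a value column (first
#'   non-year column, or named via `value`), or a numeric vector (years
#'   taken as 1..n).
#' @param value Name of the value column.
#' @return List with `slope` (value units per year), `intercept`,
#'   `std_error`.
#' @export
linear_trend <- function(series, value = NULL) {
  if (is.numeric(series) && is.null(dim(series))) {
    series <- data.frame(year = seq_along(series), value = series)
    value <- "value"
  }
  if (is.null(value)) value <- setdiff(names(series), "year")[1]
  if (nrow(series) < 3) stop("need at least 3 years")
  if (anyDuplicated(series$year)) stop("duplicate years")
  fit <- stats::lm(series[[value]] ~ series$year)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
       std_error = unname(cf[2, 2]))
}

#' Trend report for an annual emission series
#'
#' Combines [linear_trend()] and [mann_kendall()] for the emission and
#' temperature columns of an [annual_emissions()] table.
#'
#' @param annual data.frame from [annual_emissions()].
#' @return Nested list with `emission` and `temperature` entries, each
#'   holding `slope`, `intercept`, `mk_S`, `mk_tau`, `p_value`.
#' @export
trend_report <- function(annual) {
  one <- function(col) {
    lt <- linear_trend(annual, col)
    mk <- mann_kendall(annual[[col]])
    list(slope = lt$slope, intercept = lt$intercept, mk_S = mk$S,
         mk_tau = mk$tau, p_value = mk$p_value)
  }
  list(emission = one("emission"), temperature = one("mean_t_air"))
}
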