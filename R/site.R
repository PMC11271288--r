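#' Construct a site plant functional type
#'
#' A vegetation type contributing to the site isoprene flux: its leaf-level
#' emission factor, the derived canopy-level factor, which temperature
#' response it follows, and its areal cover fraction.
#'
#' @param name PFT name (e.g. "sedge", "shrub").
#' @param leaf_ef Leaf-level emission factor, nmol m^-2 s^-1, positive.
#' @param response One of `"sedge"`, `"willow"`, `"default"`.
#' @param cover_fraction Areal fraction in `[0, 1]`; may be `NA` when it is
#'   to be fitted.
#' @param canopy_scale Leaf-to-canopy scaling factor (standard-scenario
#'   LAI of 5 times the canopy factor 0.3).
#' @return An object of class `site_pft`.
#' @export
site_pft <- function(name, leaf_ef, response = c("sedge", "willow",
                                                 "default"),
                     cover_fraction = NA_real_, canopy_scale = 1.5) {
  response <- match.arg(response)
  if (leaf_ef <= 0) stop("leaf_ef must be positive")
  if (!is.na(cover_fraction) &&
      (cover_fraction < 0 || cover_fraction > 1)) {
    stop("cover_fraction must be in [0, 1]")
  }
  structure(
    list(name = name, leaf_ef = leaf_ef,
         canopy_ef = canopy_ef(leaf_ef, canopy_scale),
         response = response, cover_fraction = cover_fraction),
    class = "site_pft"
  )
}

#' @export
print.site_pft <- function(x, ...) {
  cat(sprintf("PFT %s: leaf EF %g, canopy EF %g nmol/m2/s, %s response, CF %s\n",
              x$name, x$leaf_ef, x$canopy_ef, x$response,
              ifelse(is.na(x$cover_fraction), "(to fit)",
                     format(x$cover_fraction))))
  invisible(x)
}

#' Canopy-level emission factor from a leaf-level one
#'
#' Scales a leaf-level emission factor to the canopy under the standard
#' scenario (LAI = 5) via the scalar `LAI_std x Cce = 5 x 0.3 = 1.5`. The
#' full canopy-environment model is deliberately replaced by this scalar:
#' the site flux model already externalises canopy effects into
#' `Cce x LAI/LAI_max`, and a scalar commutes with cover-fraction fitting.
#'
#' @param leaf_ef Leaf-level emission factor, nmol m^-2 s^-1, positive.
#' @param canopy_scale Scaling factor, default 1.5.
#' @return Canopy-level emission factor, nmol m^-2 s^-1.
#' @examples
#' canopy_ef(12.0)  # 18 for the sedge leaf EF
#' @export
canopy_ef <- function(leaf_ef, canopy_scale = 1.5) {
  if (any(leaf_ef <= 0)) stop("leaf_ef must be positive")
  leaf_ef * canopy_scale
}

#' Activity factors other than temperature
#'
#' `gamma_others` is the product `Cce * gamma_P * gamma_A * gamma_C *
#' gamma_SM`. Defaults: canopy factor 0.3; light, leaf-age, CO2 and
#' soil-moisture factors all 1 (light enters through the PPFD filter on
#' observations rather than a light-response formula).
#'
#' @param cce Canopy factor.
#' @param gamma_p,gamma_a,gamma_c,gamma_sm Remaining activity factors.
#' @return The scalar (or vector) product.
#' @export
gamma_others <- function(cce = 0.3, gamma_p = 1, gamma_a = 1, gamma_c = 1,
                         gamma_sm = 1) {
  if (any(c(cce, gamma_p, gamma_a, gamma_c, gamma_sm) < 0)) {
    stop("activity factors must be >= 0")
  }
  cce * gamma_p * gamma_a * gamma_c * gamma_sm
}

# Per-PFT basis flux at CF = 1:
# canopy_EF_i * (LAI/LAI_max) * gamma_T_i * gamma_others. Rows with missing
# acclimation become NA.
.pft_basis <- function(series, pfts, g_others = gamma_others(),
                       sedge_params = sedge_response_params(),
                       willow_params = willow_capacity_params(),
                       default_params = default_response_params(),
                       use_ei_basis = FALSE) {
  lai_max <- max(series$lai, na.rm = TRUE)
  if (!is.finite(lai_max) || lai_max <= 0) {
    stop("LAI must contain positive values (LAI_max > 0)")
  }
  lai_rel <- series$lai / lai_max
  B <- vapply(pfts, function(p) {
    g <- .gamma_t_by_kind(p$response, series$t_air, series$T24,
                          series$T240, default_params, sedge_params,
                          willow_params)
    ef <- if (use_ei_basis) 1 else p$canopy_ef
    ef * lai_rel * g * g_others
  }, numeric(nrow(series)))
  if (is.null(dim(B))) B <- matrix(B, nrow = nrow(series))
  colnames(B) <- vapply(pfts, function(p) p$name, "")
  B
}

#' Modelled site isoprene flux as a PFT mixture
#'
#' Per timestamp, sums over PFTs
#' `E_i * (LAI/LAI_max) * gamma_T_i * gamma_others` with total emission
#' capacity `E_i = canopy_EF_i * CF_i`, the temperature response dispatched
#' by each PFT's `response` kind, and LAI normalised by its record maximum.
#' Timestamps with missing acclimation values (spin-up) yield `NA`.
#'
#' @param series data.frame with columns `t_air` (K), `lai`, `T24`, `T240`
#'   (from [trailing_means()]); optionally `t_leaf` used instead of `t_air`
#'   when `use_leaf_temp = TRUE`.
#' @param pfts List of [site_pft()] objects with non-`NA` cover fractions.
#' @param g_others Product of non-temperature activity factors,
#'   see [gamma_others()].
#' @param sedge_params,willow_params,default_params Response parameter
#'   objects.
#' @param use_leaf_temp Drive gamma_T with `t_leaf` instead of `t_air`.
#' @return Numeric vector of modelled flux, nmol m^-2 s^-1.
#' @export
model_flux <- function(series, pfts, g_others = gamma_others(),
                       sedge_params = sedge_response_params(),
                       willow_params = willow_capacity_params(),
                       default_params = default_response_params(),
                       use_leaf_temp = FALSE) {
  if (length(pfts) == 0) stop("PFT list must be nonempty")
  if (inherits(pfts, "site_pft")) pfts <- list(pfts)
  need <- c("t_air", "lai", "T24", "T240")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop("series lacks columns: ", paste(miss, collapse = ", "),
         " (run trailing_means first)")
  }
  if (use_leaf_temp) {
    if (!"t_leaf" %in% names(series)) stop("no t_leaf column in series")
    series$t_air <- series$t_leaf
  }
  cf <- vapply(pfts, function(p) p$cover_fraction, 1)
  if (any(is.na(cf))) stop("all PFTs need a cover_fraction (or fit them)")
  B <- .pft_basis(series, pfts, g_others, sedge_params, willow_params,
                  default_params)
  drop(B %*% cf)
}

# Box-constrained least squares min ||B c - y||^2, lower <= c <= upper,
# via L-BFGS-B with analytic gradient; start from clipped OLS.
.bounded_lsq <- function(B, y, lower, upper) {
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)
  start <- tryCatch(drop(solve(BtB, Bty)), error = function(e) {
    rep(mean(pmax(upper * 0 + 0.1, lower)), ncol(B))
  })
  start <- pmin(pmax(start, lower), upper)
  fn <- function(c) sum((drop(B %*% c) - y)^2)
  gr <- function(c) drop(2 * (BtB %*% c - Bty))
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(factr = 1e4, maxit = 500))
  opt$par
}

#' Fit PFT cover fractions (or total capacities) to observed flux
#'
#' Bounded least squares of the observed half-hourly isoprene flux on the
#' per-PFT basis fluxes. In `mode = "fit-cf"` the unknowns are cover
#' fractions `CF_i` in `[0, 1]` multiplying known canopy emission factors;
#' in `mode = "fit-ei"` (the default-model convention) the unknowns are the
#' total capacities `E_i >= 0` themselves. Only daytime observations with
#' PPFD strictly exceeding `ppfd_min` (and complete acclimation) are used.
#'
#' @param obs data.frame with columns `flux` (nmol m^-2 s^-1), `t_air`,
#'   `ppfd`, `lai`, `T24`, `T240`.
#' @param pfts List of [site_pft()] objects.
#' @param ppfd_min PPFD filter threshold, umol m^-2 s^-1 (strict `>`).
#' @param mode `"fit-cf"` or `"fit-ei"`.
#' @param sum_to_one Add the constraint `sum(CF) <= 1` (off by default;
#'   fitted fractions need not exhaust the footprint).
#' @param max_kappa Condition-number threshold above which the basis is
#'   declared collinear.
#' @inheritParams model_flux
#' @return An object of class `cf_fit`: `coef` (named CFs or E_i),
#'   `r_squared` (squared Pearson correlation), `rmse`, `n_obs`,
#'   `residuals`, `fitted`, `mode`.
#' @export
fit_cover_fractions <- function(obs, pfts, ppfd_min = 300,
                                mode = c("fit-cf", "fit-ei"),
                                sum_to_one = FALSE,
                                g_others = gamma_others(),
                                sedge_params = sedge_response_params(),
                                willow_params = willow_capacity_params(),
                                default_params = default_response_params(),
                                max_kappa = 1e8) {
  mode <- match.arg(mode)
  if (inherits(pfts, "site_pft")) pfts <- list(pfts)
  need <- c("flux", "t_air", "ppfd", "lai", "T24", "T240")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    stop("observations lack columns: ", paste(miss, collapse = ", "))
  }
  keep <- obs$ppfd > ppfd_min & !is.na(obs$T24) & !is.na(obs$T240) &
    !is.na(obs$flux)
  sub <- obs[keep, , drop = FALSE]
  if (nrow(sub) == 0) stop("no observations survive the PPFD filter")
  if (nrow(sub) < 10) {
    stop(sprintf("only %d observations survive the PPFD filter; need >= 10",
                 nrow(sub)))
  }
  # LAI is normalised by the record maximum, not the filtered maximum
  B <- .pft_basis(obs, pfts, g_others, sedge_params, willow_params,
                  default_params,
                  use_ei_basis = (mode == "fit-ei"))[keep, , drop = FALSE]
  kap <- kappa(B, exact = TRUE)
  if (!is.finite(kap) || kap > max_kappa) {
    stop(sprintf(
      "PFT basis fluxes are collinear (condition number %.3g); merge PFTs",
      kap))
  }
  y <- sub$flux
  k <- ncol(B)
  lower <- rep(0, k)
  upper <- if (mode == "fit-cf") rep(1, k) else rep(Inf, k)
  coefs <- .bounded_lsq(B, y, lower, upper)
  if (mode == "fit-cf" && sum_to_one && sum(coefs) > 1) {
    # enforce the simplex face by fitting on the constraint sum(c) = s for
    # a grid of s in (0, 1]; cheap and robust for the few-PFT case
    proj <- function(s) {
      cc <- .bounded_lsq(B, y, lower, pmin(upper, s))
      if (sum(cc) > s) cc <- cc * (s / sum(cc))
      cc
    }
    cand <- lapply(seq(0.05, 1, by = 0.05), proj)
    sse <- vapply(cand, function(cc) sum((drop(B %*% cc) - y)^2), 1)
    coefs <- cand[[which.min(sse)]]
  }
  fitted <- drop(B %*% coefs)
  res <- y - fitted
  r2 <- if (stats::sd(fitted) == 0 || stats::sd(y) == 0) 0
        else stats::cor(fitted, y)^2
  names(coefs) <- colnames(B)
  structure(
    list(coef = coefs, r_squared = r2,
         rmse = sqrt(mean(res^2)), n_obs = nrow(sub),
         residuals = res, fitted = fitted, observed = y, mode = mode,
         ppfd_min = ppfd_min),
    class = "cf_fit"
  )
}

#' @export
print.cf_fit <- function(x, ...) {
  lbl <- if (x$mode == "fit-cf") "cover fractions" else "total capacities"
  cat(sprintf("Site flux fit (%s; n = %d, PPFD > %g):\n", lbl, x$n_obs,
              x$ppfd_min))
  for (nm in names(x$coef)) {
    cat(sprintf("  %-10s %.4f\n", nm, x$coef[[nm]]))
  }
  cat(sprintf("  R2 = %.3f, RMSE = %.3f nmol/m2/s\n", x$r_squared, x$rmse))
  invisible(x)
}

#' Model evaluation metrics
#'
#' R-squared (squared Pearson correlation between modelled and observed —
#' the scatter-plot convention; switch with `r2_method`) and RMSE in flux
#' units, optionally after daily-mean aggregation.
#'
#' @param modeled,observed Aligned numeric vectors, length >= 2.
#' @param aggregate `"none"` or `"daily"`; daily aggregation requires
#'   `timestamps`.
#' @param timestamps `POSIXct` vector aligned with the series (daily
#'   aggregation only).
#' @param r2_method `"pearson"` (squared correlation) or `"ss"`
#'   (1 - SSE/SST).
#' @return List with `r_squared`, `rmse`, `n`, and (daily mode) a `daily`
#'   data.frame with per-day means and standard deviations.
#' @export
evaluate_fit <- function(modeled, observed, aggregate = c("none", "daily"),
                         timestamps = NULL,
                         r2_method = c("pearson", "ss")) {
  aggregate <- match.arg(aggregate)
  r2_method <- match.arg(r2_method)
  if (length(modeled) != length(observed)) {
    stop("modeled and observed must have the same length")
  }
  keep <- !is.na(modeled) & !is.na(observed)
  modeled <- modeled[keep]; observed <- observed[keep]
  daily <- NULL
  if (aggregate == "daily") {
    if (is.null(timestamps)) stop("daily aggregation needs timestamps")
    day <- as.Date(timestamps[keep])
    daily <- data.frame(
      day = sort(unique(day)),
      modeled = tapply(modeled, day, mean),
      observed = tapply(observed, day, mean),
      modeled_sd = tapply(modeled, day, stats::sd),
      observed_sd = tapply(observed, day, stats::sd),
      row.names = NULL)
    modeled <- daily$modeled; observed <- daily$observed
  }
  if (length(modeled) < 2) stop("need at least 2 aligned observations")
  r2 <- if (r2_method == "pearson") {
    if (stats::sd(modeled) == 0 || stats::sd(observed) == 0) 0
    else stats::cor(modeled, observed)^2
  } else {
    1 - sum((observed - modeled)^2) /
      sum((observed - mean(observed))^2)
  }
  out <- list(r_squared = r2,
              rmse = sqrt(mean((modeled - observed)^2)),
              n = length(modeled))
  if (!is.null(daily)) out$daily <- daily
  out
}
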