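# CSV dialect is fixed: comma-separated, UTF-8, ISO-8601 timestamps (UTC),
# "." decimal, empty fields for missing values.

.parse_timestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%d"))
  if (any(is.na(out))) {
    stop("unparseable timestamp: ", x[is.na(out)][1])
  }
  out
}

.to_kelvin <- function(x, unit) {
  switch(unit, K = x, C = celsius_to_kelvin(x),
         stop("temperature unit must be 'K' or 'C'"))
}

#' Read a meteorological CSV
#'
#' Columns: `timestamp` (ISO 8601), `t_air`, optional `t_leaf`, `ppfd`,
#' `lai`. Temperatures are converted to Kelvin according to `temp_unit`
#' (or a `temp_unit` column holding "K"/"C").
#'
#' @param path CSV path.
#' @param temp_unit `"K"` or `"C"`; ignored when the file carries a
#'   `temp_unit` column.
#' @return data.frame with `timestamp` (POSIXct UTC) and temperatures in K.
#' @export
read_met_csv <- function(path, temp_unit = "K") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "t_air") %in% names(df))) {
    stop("met CSV needs columns timestamp, t_air")
  }
  unit <- if ("temp_unit" %in% names(df)) df$temp_unit[1] else temp_unit
  df$timestamp <- .parse_timestamp(df$timestamp)
  df$t_air <- .to_kelvin(df$t_air, unit)
  if ("t_leaf" %in% names(df)) df$t_leaf <- .to_kelvin(df$t_leaf, unit)
  df$temp_unit <- NULL
  df
}

#' Read a half-hourly flux CSV
#'
#' Columns: `timestamp, flux, flux_units, t_air, ppfd, lai` (optional
#' `t_leaf`). `flux_units` is `nmol_m2_s` or `mg_m2_h`; the latter is
#' converted with the isoprene molar mass (68.12 g mol^-1).
#'
#' @inheritParams read_met_csv
#' @return data.frame with flux in nmol m^-2 s^-1 and temperatures in K.
#' @export
read_flux_csv <- function(path, temp_unit = "K") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "flux", "t_air", "ppfd", "lai")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("flux CSV lacks columns: ", paste(miss, collapse = ", "))
  }
  df$timestamp <- .parse_timestamp(df$timestamp)
  unit <- if ("temp_unit" %in% names(df)) df$temp_unit[1] else temp_unit
  df$t_air <- .to_kelvin(df$t_air, unit)
  if ("t_leaf" %in% names(df)) df$t_leaf <- .to_kelvin(df$t_leaf, unit)
  if ("flux_units" %in% names(df)) {
    fu <- unique(df$flux_units)
    if (length(fu) > 1) stop("mixed flux_units in one file")
    if (fu == "mg_m2_h") {
      df$flux <- df$flux * 1e6 / ISOPRENE_MOLAR_MASS / 3600
    } else if (fu != "nmol_m2_s") {
      stop("flux_units must be nmol_m2_s or mg_m2_h")
    }
    df$flux_units <- NULL
  }
  df$temp_unit <- NULL
  df
}

#' Read chamber-experiment CSVs
#'
#' The steps file has columns `experiment_id, species, step_temp,
#' emission_rate, ppfd` and optional `blank_rate`; the companion history
#' file has `experiment_id, day_offset, daily_mean_temp` with day_offset 1
#' = most recent day. Temperatures convert per `temp_unit`.
#'
#' @param steps_path,history_path CSV paths (history optional).
#' @inheritParams read_met_csv
#' @return List of [chamber_experiment()] objects.
#' @export
read_chamber_csv <- function(steps_path, history_path = NULL,
                             temp_unit = "K") {
  df <- utils::read.csv(steps_path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "species", "step_temp", "emission_rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("chamber CSV lacks columns: ", paste(miss, collapse = ", "))
  }
  df$step_temp <- .to_kelvin(df$step_temp, temp_unit)
  hist <- NULL
  if (!is.null(history_path)) {
    hist <- utils::read.csv(history_path, stringsAsFactors = FALSE)
    hist$daily_mean_temp <- .to_kelvin(hist$daily_mean_temp, temp_unit)
  }
  lapply(split(df, df$experiment_id), function(g) {
    g <- g[order(g$step_temp), ]
    pd <- numeric()
    if (!is.null(hist)) {
      h <- hist[hist$experiment_id == g$experiment_id[1], ]
      pd <- h$daily_mean_temp[order(h$day_offset)]
    }
    chamber_experiment(
      species_label = g$species[1], step_temp = g$step_temp,
      emission_rate = g$emission_rate,
      ppfd = if ("ppfd" %in% names(g)) g$ppfd[1] else 1000,
      prior_daily_means = pd,
      blank_rate = if ("blank_rate" %in% names(g)) g$blank_rate else NULL)
  })
}

#' Write chamber experiments to the package CSV dialect
#'
#' @param experiments List of [chamber_experiment()] objects.
#' @param steps_path,history_path Output CSV paths.
#' @return Invisibly, the steps path.
#' @export
write_chamber_csv <- function(experiments, steps_path,
                              history_path = NULL) {
  steps <- do.call(rbind, lapply(seq_along(experiments), function(i) {
    e <- experiments[[i]]
    data.frame(experiment_id = i, species = e$species_label,
               step_temp = e$steps$temp, emission_rate = e$steps$emission,
               ppfd = e$ppfd)
  }))
  utils::write.csv(steps, steps_path, row.names = FALSE, quote = FALSE)
  if (!is.null(history_path)) {
    hist <- do.call(rbind, lapply(seq_along(experiments), function(i) {
      e <- experiments[[i]]
      if (!length(e$prior_daily_means)) return(NULL)
      data.frame(experiment_id = i,
                 day_offset = seq_along(e$prior_daily_means),
                 daily_mean_temp = e$prior_daily_means)
    }))
    utils::write.csv(hist, history_path, row.names = FALSE, quote = FALSE)
  }
  invisible(steps_path)
}

#' Write a flux/met series to the package CSV dialect
#'
#' @param series data.frame with a `timestamp` column (POSIXct).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_series_csv <- function(series, path) {
  series$timestamp <- format(series$timestamp, "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC")
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

.config_defaults <- function() {
  list(cce = 0.3, r = GAS_CONSTANT_KJ, ppfd_min = 300, t_max = 308.15,
       canopy_scale = 1.5, pfts = list())
}

.known_keys <- c("cce", "r", "ppfd_min", "t_max", "canopy_scale", "pfts")
.known_pft_keys <- c("leaf_ef", "response", "cover_fraction")

#' Load and validate a site/analysis configuration
#'
#' YAML file with optional top-level keys `cce`, `r`, `ppfd_min`, `t_max`,
#' `canopy_scale` and a `pfts` mapping of PFT name to `leaf_ef`,
#' `response`, optional `cover_fraction`. Missing keys receive defaults;
#' unknown keys are rejected; physically invalid values (negative emission
#' factor, cce outside (0, 1], ...) are errors. An empty file yields the
#' full default configuration.
#'
#' @param path YAML file path.
#' @return Validated configuration list with a `pft_objects` entry of
#'   [site_pft()] objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .known_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.config_defaults(), raw)
  if (!is.numeric(cfg$cce) || cfg$cce <= 0 || cfg$cce > 1) {
    stop("cce must be in (0, 1]")
  }
  if (cfg$r <= 0) stop("gas constant r must be positive")
  if (cfg$ppfd_min < 0) stop("ppfd_min must be >= 0")
  if (cfg$t_max <= .T_MIN || cfg$t_max >= .T_MAX) {
    stop("t_max outside plausible range")
  }
  if (cfg$canopy_scale <= 0) stop("canopy_scale must be positive")
  cfg$pft_objects <- lapply(names(cfg$pfts), function(nm) {
    p <- cfg$pfts[[nm]]
    bad <- setdiff(names(p), .known_pft_keys)
    if (length(bad)) {
      stop(sprintf("unknown keys in pft '%s': %s", nm,
                   paste(bad, collapse = ", ")))
    }
    if (is.null(p$leaf_ef)) stop(sprintf("pft '%s' lacks leaf_ef", nm))
    if (p$leaf_ef <= 0) stop(sprintf("pft '%s': leaf_ef must be positive",
                                     nm))
    site_pft(nm, p$leaf_ef,
             response = if (is.null(p$response)) "default" else p$response,
             cover_fraction = if (is.null(p$cover_fraction)) NA_real_
                              else p$cover_fraction,
             canopy_scale = cfg$canopy_scale)
  })
  names(cfg$pft_objects) <- names(cfg$pfts)
  cfg
}

#' Serialise a configuration back to YAML
#'
#' Writes the normalised configuration (defaults injected, derived objects
#' dropped), so `dump_config(load_config(x))` is idempotent.
#'
#' @param cfg Configuration list from [load_config()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
dump_config <- function(cfg, path) {
  cfg$pft_objects <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}
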