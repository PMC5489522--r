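#' Convert electrical conductivity to Na+ molarity
#'
#' Linear conversion between the electrical conductivity of field water
#' (dS m-1) and the Na+ concentration of a dilute NaCl solution (mM). The
#' default 10 mM per dS m-1 is the conventional dilute-NaCl approximation.
#'
#' @param ec Electrical conductivity (dS m-1), >= 0.
#' @param factor Conversion factor (mM per dS m-1).
#' @return Na+ concentration (mM).
#' @export
ec_to_molarity <- function(ec, factor = 10) {
  if (any(ec < 0)) stop("'ec' must be >= 0", call. = FALSE)
  ec * factor
}

#' Define a seasonal field-water salinity scenario
#'
#' Two archetypal seasonal dynamics of field-water salinity are built in,
#' mirroring contrasting irrigation-management regimes:
#' * `early_peak` - salinity rises quickly to its maximum within the first
#'   third of the season (evapo-concentration during a water-holding
#'   period) and decays sharply once fresh-water flow is restored,
#'   returning to a low baseline;
#' * `gradual_ramp` - salinity increases progressively until mid-season
#'   and then stays constant to harvest (saline soils feeding salts into
#'   the irrigation water);
#' * `constant` - a flat series (hydroponic-style treatment);
#' * `custom` - a user-supplied EC vector.
#'
#' @param pattern One of `"early_peak"`, `"gradual_ramp"`, `"constant"`,
#'   `"custom"`.
#' @param peak_ec Maximum electrical conductivity (dS m-1); defaults:
#'   3.5 for `early_peak`, 2.5 for `gradual_ramp`.
#' @param baseline_ec Background EC outside the stress period (dS m-1).
#' @param peak_day Day the early peak is reached (default: 25% of season).
#' @param decay_days Length of the post-peak decay of `early_peak` (days).
#' @param plateau_day Day the gradual ramp reaches its plateau (default:
#'   mid-season).
#' @param conversion_factor mM of Na+ per dS m-1, see [ec_to_molarity()].
#' @param values EC vector for `pattern = "custom"`.
#' @return An object of class `salinity_scenario`.
#' @export
salinity_scenario <- function(pattern = c("early_peak", "gradual_ramp",
                                          "constant", "custom"),
                              peak_ec = NULL, baseline_ec = 0.3,
                              peak_day = NULL, decay_days = 15,
                              plateau_day = NULL, conversion_factor = 10,
                              values = NULL) {
  pattern <- match.arg(pattern)
  if (is.null(peak_ec))
    peak_ec <- switch(pattern, early_peak = 3.5, gradual_ramp = 2.5,
                      constant = 3.5, custom = NA_real_)
  if (pattern == "custom" && is.null(values))
    stop("pattern 'custom' requires 'values'", call. = FALSE)
  if (pattern != "custom" && (peak_ec < 0 || baseline_ec < 0))
    stop("EC levels must be >= 0", call. = FALSE)
  structure(list(pattern = pattern, peak_ec = peak_ec,
                 baseline_ec = baseline_ec, peak_day = peak_day,
                 decay_days = decay_days, plateau_day = plateau_day,
                 conversion_factor = conversion_factor, values = values),
            class = "salinity_scenario")
}

#' Generate a daily salinity series from a scenario
#'
#' @param scenario A [salinity_scenario()] object.
#' @param season_length Number of days, > 0.
#' @param as_molarity Return mM of Na+ (default) rather than EC (dS m-1).
#' @return Numeric vector of length `season_length`.
#' @export
make_salinity_series <- function(scenario, season_length,
                                 as_molarity = TRUE) {
  if (season_length < 1)
    stop("'season_length' must be > 0", call. = FALSE)
  d <- seq_len(season_length)
  ec <- switch(scenario$pattern,
    constant = rep(scenario$peak_ec, season_length),
    custom = {
      v <- scenario$values
      if (length(v) != season_length)
        stop("custom values must match 'season_length'", call. = FALSE)
      v
    },
    early_peak = {
      pk <- scenario$peak_day %||% max(1, round(0.25 * season_length))
      if (pk > season_length %/% 3)
        pk <- season_length %/% 3        # peak stays in the first third
      rise <- scenario$baseline_ec +
        (scenario$peak_ec - scenario$baseline_ec) * (d / pk)
      fall <- scenario$baseline_ec +
        (scenario$peak_ec - scenario$baseline_ec) *
          exp(-(d - pk) / (scenario$decay_days / 3))
      ifelse(d <= pk, rise, fall)
    },
    gradual_ramp = {
      pl <- scenario$plateau_day %||% round(season_length / 2)
      ec <- scenario$baseline_ec +
        (scenario$peak_ec - scenario$baseline_ec) * pmin(1, d / pl)
      ec
    }
  )
  ec <- pmax(0, ec)
  if (as_molarity) ec_to_molarity(ec, scenario$conversion_factor) else ec
}

#' Generate a synthetic temperate-season weather series
#'
#' Seeded, reproducible daily weather for a temperate rice season
#' (spring sowing, late-summer harvest): temperature and radiation follow
#' smooth half-sine seasonal curves with bounded autocorrelated noise;
#' relative humidity is confined to a configurable band; reference
#' evapotranspiration is derived from radiation and temperature with
#' bounded noise. Intended as a stand-in for multi-year reanalysis
#' retrievals when exploring trait sensitivity: distinct seeds emulate
#' distinct seasons.
#'
#' @param season_length Number of days, > 0.
#' @param seed Integer seed; the series is a pure function of
#'   (parameters, seed).
#' @param tmean_range Seasonal minimum and maximum of the smooth mean
#'   temperature curve (degrees C).
#' @param radiation_range Seasonal range of the radiation curve
#'   (MJ m-2 d-1).
#' @param rh_band Relative-humidity band (%), samples never leave it.
#' @param noise_sd Standard deviation of the day-to-day temperature noise
#'   (degrees C); radiation and et0 noise scale from it.
#' @return A data frame with columns `day`, `tmean`, `radiation`, `rh`,
#'   `et0`.
#' @export
make_weather <- function(season_length, seed,
                         tmean_range = c(16, 25),
                         radiation_range = c(14, 24),
                         rh_band = c(58, 92),
                         noise_sd = 1.5) {
  if (season_length < 1)
    stop("'season_length' must be > 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- seq_len(season_length)
  phase <- sin(pi * d / season_length)     # 0 at sowing/harvest, 1 mid
  ar1 <- function(n, rho = 0.6) {
    e <- stats::rnorm(n)
    as.numeric(stats::filter(e, rho, method = "recursive")) *
      sqrt(1 - rho^2)
  }
  tmean <- tmean_range[1] + diff(tmean_range) * phase +
    noise_sd * ar1(season_length)
  radiation <- pmax(1, radiation_range[1] + diff(radiation_range) * phase +
                      2 * noise_sd * ar1(season_length))
  rh_mid <- mean(rh_band)
  rh <- clamp(rh_mid + 0.35 * diff(rh_band) * ar1(season_length),
              rh_band[1], rh_band[2])
  et0 <- pmax(0.5, 0.18 * radiation + 0.06 * (tmean - 10) +
                0.3 * ar1(season_length))
  data.frame(day = d, tmean = tmean, radiation = radiation, rh = rh,
             et0 = et0)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read and write the delimited weather / salinity formats
#'
#' The weather file is tab-separated with header columns `day`, `tmean`,
#' `radiation`, `rh`, `et0`; the salinity file has columns `day` and
#' either `na_mm` (mM) or `ec` (dS m-1, converted on read).
#'
#' @param weather Data frame as produced by [make_weather()].
#' @param path File path.
#' @return `read_weather()` returns the weather data frame;
#'   `read_salinity()` a numeric vector of mM; writers return the path
#'   invisibly.
#' @export
write_weather <- function(weather, path) {
  utils::write.table(weather, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  w <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("day", "tmean", "radiation", "rh", "et0")
  missing <- setdiff(need, names(w))
  if (length(missing))
    stop("weather file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  w
}

#' @rdname write_weather
#' @param salinity Numeric vector of daily Na+ concentrations (mM).
#' @export
write_salinity <- function(salinity, path) {
  utils::write.table(
    data.frame(day = seq_along(salinity), na_mm = salinity),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather
#' @param conversion_factor mM per dS m-1, used when the file carries EC.
#' @export
read_salinity <- function(path, conversion_factor = 10) {
  s <- utils::read.table(path, header = TRUE, sep = "\t")
  if ("na_mm" %in% names(s)) return(as.numeric(s$na_mm))
  if ("ec" %in% names(s))
    return(ec_to_molarity(as.numeric(s$ec), conversion_factor))
  stop("salinity file needs a 'na_mm' or 'ec' column", call. = FALSE)
}
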