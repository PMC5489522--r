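#' Parameters of the minimal multilayer host crop engine
#'
#' The host is a deliberately small SUCROS/WOFOST-style daily engine:
#' thermal-time phenology, Beer-law light interception, radiation-use
#' efficiency (RUE) growth, tabulated dry-matter partitioning, first-order
#' maintenance respiration with a Q10 temperature response, and a canopy
#' described by `n_layers` equal-biomass layers ordered by tissue age
#' (layer 1 = bottom = oldest). It exists to provide the coupling points
#' the salinity module needs (transpiration, DVS, partitioning, per-layer
#' leaf biomass) rather than to reproduce any particular full crop model.
#'
#' @param tt_anthesis Thermal time from emergence to anthesis (degree-days).
#' @param tt_maturity Thermal time from anthesis to maturity (degree-days).
#' @param t_base Base temperature for thermal time (degrees C).
#' @param rue Radiation-use efficiency (g dry matter per MJ intercepted
#'   PAR).
#' @param k_ext Canopy light extinction coefficient (unitless).
#' @param par_fraction Fraction of global radiation that is PAR.
#' @param kc Crop transpiration coefficient (mm transpired per mm
#'   intercepted reference evapotranspiration).
#' @param sla_table Two-column matrix (dvs, sla m2 kg-1): potential
#'   specific leaf area of new growth, interpolated over DVS.
#' @param partitioning Four-column matrix (dvs, leaf, culm, panicle):
#'   dry-matter partitioning fractions, each row summing to 1,
#'   interpolated over DVS.
#' @param maint_coef Named vector of maintenance-respiration coefficients
#'   (g g-1 d-1 at 25 C) for `leaf`, `culm`, `panicle`.
#' @param q10 Q10 of maintenance respiration.
#' @param growth_efficiency Conversion efficiency of assimilates to
#'   structural dry matter (g g-1).
#' @param rd_base Baseline relative leaf death rate before maturity ramp
#'   (d-1).
#' @param rd_maturity Additional relative death rate reached at DVS = 2
#'   (d-1), ramped linearly over DVS 1-2.
#' @param n_layers Number of canopy layers.
#' @param plant_density Plant density (plants ha-1).
#' @param grain_fraction Grain mass fraction of final panicle biomass.
#' @param remob_fraction Fraction of the culm biomass present at anthesis
#'   that can be remobilized to the panicle during grain filling.
#' @param remob_rate Relative daily remobilization rate of the remaining
#'   allowance (d-1).
#' @param init_leaf,init_culm Initial biomass of the transplanted
#'   seedlings (kg ha-1).
#'
#' @return An object of class `host_parameters`.
#' @export
host_parameters <- function(tt_anthesis = 1100,
                            tt_maturity = 600,
                            t_base = 8,
                            rue = 3.0,
                            k_ext = 0.5,
                            par_fraction = 0.5,
                            kc = 1.05,
                            sla_table = cbind(dvs = c(0, 0.5, 1, 2),
                                              sla = c(28, 24, 18, 16)),
                            partitioning = cbind(
                              dvs = c(0, 0.4, 0.75, 1, 1.2, 2),
                              leaf = c(0.55, 0.55, 0.30, 0.05, 0, 0),
                              culm = c(0.45, 0.45, 0.55, 0.20, 0, 0),
                              panicle = c(0, 0, 0.15, 0.75, 1, 1)),
                            maint_coef = c(leaf = 0.016, culm = 0.006,
                                           panicle = 0.008),
                            q10 = 2,
                            growth_efficiency = 0.74,
                            rd_base = 0.001,
                            rd_maturity = 0.03,
                            n_layers = 5,
                            plant_density = 2.5e6,
                            grain_fraction = 0.9,
                            remob_fraction = 0.3,
                            remob_rate = 0.04,
                            init_leaf = 60,
                            init_culm = 30) {
  p <- as.list(environment())
  part_sums <- rowSums(p$partitioning[, c("leaf", "culm", "panicle")])
  if (any(abs(part_sums - 1) > 1e-9))
    stop("partitioning fractions must sum to 1 at every DVS node",
         call. = FALSE)
  if (p$n_layers < 1) stop("'n_layers' must be >= 1", call. = FALSE)
  rates <- c(p$rue, p$kc, unlist(p$maint_coef), p$rd_base, p$rd_maturity)
  if (any(rates < 0)) stop("host rates must be >= 0", call. = FALSE)
  structure(p, class = "host_parameters")
}

#' Crop state of the host engine
#'
#' @param host A [host_parameters()] object used for initial values.
#' @return An object of class `crop_state` holding DVS, thermal time,
#'   per-layer leaf biomass (kg ha-1, bottom first), culm and panicle
#'   biomass, dead-leaf biomass, LAI, current transpiration, panicle
#'   partitioning share and plant density.
#' @export
crop_state <- function(host = host_parameters()) {
  n <- host$n_layers
  sla0 <- interp_table(host$sla_table, 0)
  structure(list(
    dvs = 0, tt = 0,
    leaf_biomass_by_layer = rep(host$init_leaf / n, n),
    culm_biomass = host$init_culm,
    panicle_biomass = 0,
    dead_leaf_biomass = 0,
    lai = host$init_leaf * sla0 / 1e4,
    tr_act = 0,
    par_p = 0,
    remob_pool = NA_real_,
    plant_density = host$plant_density,
    n_layers = n
  ), class = "crop_state")
}

interp_table <- function(tab, dvs, col = 2) {
  stats::approx(tab[, 1], tab[, col], xout = dvs, rule = 2)$y
}

#' Advance phenology by one day of thermal time
#'
#' DVS accumulates linearly in thermal time: 0 to 1 over `tt_anthesis`
#' degree-days above `t_base`, then 1 to 2 over `tt_maturity`, capped at 2.
#'
#' @param state A [crop_state()] object.
#' @param tmean Mean air temperature (degrees C).
#' @param host A [host_parameters()] object.
#' @return The state with updated `tt` and `dvs`.
#' @export
advance_phenology <- function(state, tmean, host) {
  state$tt <- state$tt + max(0, tmean - host$t_base)
  state$dvs <- if (state$tt <= host$tt_anthesis) {
    state$tt / host$tt_anthesis
  } else {
    min(2, 1 + (state$tt - host$tt_anthesis) / host$tt_maturity)
  }
  state
}

# Conservative re-binning of a per-layer quantity when layers are re-cut
# into equal-biomass segments. `m` are segment masses bottom->top, `x` the
# per-segment totals of the transported quantity; returns per-segment totals
# over n equal-mass segments. Exactly conservative.
reslice_layers <- function(m, x, n) {
  total <- sum(m)
  if (total <= 0) return(list(m = rep(0, n), x = rep(0, n)))
  k <- length(m)
  old_hi <- cumsum(m)
  old_lo <- old_hi - m
  dens <- numeric(k)
  pos <- m > 0
  dens[pos] <- x[pos] / m[pos]
  step <- total / n
  new_lo <- step * (seq_len(n) - 1)
  # overlap of every (new segment, old segment) pair along the cumulative
  # biomass axis
  ov <- pmin(matrix(new_lo + step, n, k),
             matrix(old_hi, n, k, byrow = TRUE)) -
        pmax(matrix(new_lo, n, k),
             matrix(old_lo, n, k, byrow = TRUE))
  ov[ov < 0] <- 0
  list(m = rep(step, n),
       x = as.numeric(ov %*% dens))
}

# Fraction of intercepted light absorbed by each layer (bottom first),
# assuming LAI is spread equally over layers; used to weight per-layer
# photosynthesis stress by the light each layer actually receives.
layer_light_weights <- function(lai, k_ext, n) {
  if (lai <= 0) return(rep(1 / n, n))
  lai_layer <- lai / n
  above <- (n - seq_len(n)) * lai_layer      # LAI above layer i
  absorbed <- exp(-k_ext * above) - exp(-k_ext * (above + lai_layer))
  absorbed / sum(absorbed)
}

#' One day of crop growth under given stress factors
#'
#' Runs the daily carbon and canopy bookkeeping: Beer-law interception of
#' PAR, gross assimilation scaled by the light-weighted photosynthesis
#' stress, Q10 maintenance respiration (leaf and culm terms amplified by
#' `1 + mresp_f`), conversion to structural growth, tabulated partitioning
#' with the culm increment scaled by `cvs_stress` and the panicle increment
#' by `1 - sterility_f` (the photosynthate withheld by these factors is an
#' explicit stress loss, so daily carbon closes exactly), leaf-area update
#' through SLA times `sla_stress`, senescence (bottom-weighted, amplified
#' per layer by `1 + k_sen * (1 - RPn_i)`) and a re-cut of the canopy into
#' equal-biomass layers. Transpiration is `kc * et0 * interception`.
#'
#' @param state A [crop_state()] object.
#' @param env A [daily_environment()] object.
#' @param stress A `stress_factors` object (see [stress_factors()] /
#'   [neutral_stress()]).
#' @param host A [host_parameters()] object.
#' @param k_sen Senescence amplification coefficient.
#' @param leaf_na Optional per-layer leaf Na+ pools (mg ha-1) transported
#'   through senescence and re-slicing alongside biomass.
#' @param culm_na Culm Na+ pool (mg ha-1); the share bound to remobilized
#'   stem tissue is fixed into the dead ledger.
#' @param part,sla Optional precomputed partitioning fractions
#'   (`c(leaf, culm, panicle)`) and SLA at the current DVS, bypassing the
#'   table interpolation (used by [run_season()]).
#' @param retain_senescent_na Keep the Na+ of dying leaf tissue in its
#'   (living) layer instead of moving it to the dead ledger.
#' @return A list with the updated `state`, updated `leaf_na` and
#'   `culm_na`, `na_died` (leaf Na+ moved to dead tissue, mg ha-1),
#'   `na_culm_fixed` (culm Na+ fixed in structural tissue, mg ha-1) and a
#'   `carbon` list with the day's gross assimilation, respiration,
#'   increments, remobilization and stress loss (all kg ha-1).
#' @export
daily_growth <- function(state, env, stress, host, k_sen = 1,
                         leaf_na = rep(0, state$n_layers),
                         culm_na = 0, part = NULL, sla = NULL,
                         retain_senescent_na = FALSE) {
  n <- state$n_layers
  fint <- 1 - exp(-host$k_ext * state$lai)
  state$tr_act <- host$kc * env$et0 * fint

  # gross assimilation, reduced by light-weighted photosynthesis stress
  w <- layer_light_weights(state$lai, host$k_ext, n)
  rpn_eff <- sum(w * stress$rpn_by_layer)
  par_mj <- env$radiation * host$par_fraction
  gross <- host$rue * par_mj * fint * rpn_eff * 10   # g m-2 -> kg ha-1

  # maintenance respiration (Q10), salt-amplified for leaves and culms
  tfac <- host$q10^((env$tmean - 25) / 10)
  mc <- host$maint_coef
  maint <- tfac * ((mc[["leaf"]] * sum(state$leaf_biomass_by_layer) +
                    mc[["culm"]] * state$culm_biomass) *
                     (1 + stress$mresp_f) +
                   mc[["panicle"]] * state$panicle_biomass)
  net <- max(0, host$growth_efficiency * (gross - maint))

  # partitioning, with osmotic/sterility withholding as explicit losses
  dvs <- state$dvs
  if (is.null(part)) {
    part <- c(interp_table(host$partitioning, dvs, col = 2),
              interp_table(host$partitioning, dvs, col = 3),
              interp_table(host$partitioning, dvs, col = 4))
  }
  pl <- part[1]; pc <- part[2]; pp <- part[3]
  state$par_p <- pp
  leaf_inc <- net * pl
  culm_inc <- net * pc * stress$cvs_stress
  pan_inc <- net * pp * (1 - stress$sterility_f)
  stress_loss <- net - leaf_inc - culm_inc - pan_inc

  # new leaf growth enters the top (youngest) layer
  if (is.null(sla)) sla <- interp_table(host$sla_table, dvs)
  m <- state$leaf_biomass_by_layer
  m[n] <- m[n] + leaf_inc
  lai <- state$lai + leaf_inc * sla * stress$sla_stress / 1e4

  # senescence: relative death rate rises towards maturity and is
  # amplified in salt-stressed layers
  rd <- host$rd_base + host$rd_maturity * max(0, dvs - 1)
  rd_layer <- pmin(1, rd * (1 + k_sen * (1 - stress$rpn_by_layer)))
  died <- m * rd_layer
  # by default the Na+ of dying tissue follows it into the dead ledger
  # (old leaves as a disposable sink); optionally it stays in the layer
  na_died <- if (retain_senescent_na) numeric(n) else leaf_na * rd_layer
  lai_died <- if (sum(m) > 0) state$lai * sum(died) / sum(m) else 0
  m <- m - died
  leaf_na <- leaf_na - na_died
  lai <- max(0, lai - lai_died)
  state$dead_leaf_biomass <- state$dead_leaf_biomass + sum(died)

  # re-cut the canopy into equal-biomass layers (oldest at the bottom)
  rs <- reslice_layers(m, leaf_na, n)
  state$leaf_biomass_by_layer <- rs$m
  leaf_na <- rs$x
  state$lai <- lai
  state$culm_biomass <- state$culm_biomass + culm_inc
  state$panicle_biomass <- state$panicle_biomass + pan_inc

  # stem-reserve remobilization to the panicle during grain filling; the
  # Na+ of the hollowed-out culm fraction is fixed in structural tissue
  # (moved to the dead ledger), keeping the active culm concentration
  # unchanged
  remob <- 0
  na_culm_fixed <- 0
  if (state$dvs >= 1 && host$remob_fraction > 0) {
    if (is.na(state$remob_pool))
      state$remob_pool <- host$remob_fraction * state$culm_biomass
    remob <- min(host$remob_rate * state$remob_pool, state$culm_biomass)
    if (state$culm_biomass > 0)
      na_culm_fixed <- culm_na * remob / state$culm_biomass
    culm_na <- culm_na - na_culm_fixed
    state$remob_pool <- state$remob_pool - remob
    state$culm_biomass <- state$culm_biomass - remob
    state$panicle_biomass <- state$panicle_biomass + remob
  }
  if (any(c(state$leaf_biomass_by_layer, state$culm_biomass,
            state$panicle_biomass) < -1e-12))
    stop("internal error: negative biomass", call. = FALSE)

  list(state = state, leaf_na = leaf_na, na_died = sum(na_died),
       culm_na = culm_na, na_culm_fixed = na_culm_fixed,
       carbon = list(gross = gross, maint = as.numeric(maint), net = net,
                     leaf_inc = leaf_inc, culm_inc = culm_inc,
                     pan_inc = pan_inc, remob = remob,
                     stress_loss = stress_loss, rpn_eff = rpn_eff))
}

#' Run a full season of the coupled salinity-crop model
#'
#' Daily loop: phenology, stress factors from yesterday's tissue
#' concentrations and today's external salinity, host growth and canopy
#' bookkeeping, shoot Na+ uptake driven by today's transpiration, and Na+
#' allocation among culm, panicle and leaf layers. With `salt_enabled =
#' FALSE` (or a zero salinity series) the salinity module is a strict
#' no-op and the trajectory equals a host-only run.
#'
#' @param weather A data frame with one row per day and columns `tmean`,
#'   `radiation`, `rh`, `et0` (see [make_weather()]).
#' @param salinity Numeric vector of external Na+ concentrations (mM), one
#'   per day, or a single value recycled over the season.
#' @param params A [trait_parameters()] object.
#' @param aux An [auxiliary_constants()] object.
#' @param host A [host_parameters()] object.
#' @param modes Equation-mode switches, see [default_modes()].
#' @param salt_enabled Disable the salinity module entirely.
#' @param daily Keep the daily output table (default TRUE); `FALSE` skips
#'   that bookkeeping and is used for large simulation batches where only
#'   the final summaries matter.
#' @return An object of class `simulation_result`: list with `daily` (data
#'   frame, one row per day), `yield` (kg ha-1), `agb` (final aboveground
#'   biomass, kg ha-1), `cumulative_fertility` (fraction), `final_pools`
#'   (a [sodium_pools()] object) and `na_balance_error` (relative closure
#'   error of the Na+ mass balance).
#' @export
run_season <- function(weather, salinity = 0,
                       params = trait_parameters(),
                       aux = auxiliary_constants(),
                       host = host_parameters(),
                       modes = default_modes(),
                       salt_enabled = TRUE, daily = TRUE) {
  ndays <- nrow(weather)
  if (ndays < 1) stop("empty weather series", call. = FALSE)
  if (length(salinity) == 1) salinity <- rep(salinity, ndays)
  if (length(salinity) != ndays)
    stop("salinity series must match the weather series length",
         call. = FALSE)
  if (any(salinity < 0)) stop("salinity must be >= 0", call. = FALSE)

  state <- crop_state(host)
  pools <- sodium_pools(host$n_layers)
  cum_uptake <- 0
  fertility <- 1

  # phenology depends on temperature alone: precompute the DVS series and
  # the tabulated curves along it
  tt <- cumsum(pmax(0, weather$tmean - host$t_base))
  dvs_series <- ifelse(tt <= host$tt_anthesis, tt / host$tt_anthesis,
                       pmin(2, 1 + (tt - host$tt_anthesis) /
                              host$tt_maturity))
  pl_s <- interp_table(host$partitioning, dvs_series, col = 2)
  pc_s <- interp_table(host$partitioning, dvs_series, col = 3)
  pp_s <- interp_table(host$partitioning, dvs_series, col = 4)
  sla_s <- interp_table(host$sla_table, dvs_series)

  cols <- c("day", "dvs", "lai", "agb", "leaf_biomass", "culm_biomass",
            "panicle_biomass", "dead_leaf_biomass", "tr_act", "na_ext",
            "na_uptake", "culm_na", "panicle_na", "leaf_na", "dead_na",
            "na_leaf_mean", "rpn_eff", "mresp_f", "sterility_f",
            "sla_stress", "cvs_stress", "gross", "maint", "stress_loss")
  out <- if (daily) {
    matrix(NA_real_, nrow = ndays, ncol = length(cols),
           dimnames = list(NULL, cols))
  }

  w_tmean <- weather$tmean
  w_rad <- weather$radiation
  w_rh <- weather$rh
  w_et0 <- weather$et0
  neutral <- neutral_stress(host$n_layers)
  k_sen <- modes$k_sen %||% 1
  for (d in seq_len(ndays)) {
    env <- list(tmean = w_tmean[d], radiation = w_rad[d],
                rh = w_rh[d], et0 = w_et0[d],
                na_ext = if (salt_enabled) salinity[d] else 0)
    if (env$rh < 0 || env$rh > 100)
      stop("relative humidity must be within [0, 100] %", call. = FALSE)
    state$tt <- tt[d]
    state$dvs <- dvs_series[d]
    stress <- if (salt_enabled) {
      stress_factors(pools, state, env$na_ext, params, aux, modes)
    } else {
      neutral
    }
    g <- daily_growth(state, env, stress, host, k_sen = k_sen,
                      leaf_na = pools$leaf_na_by_layer,
                      culm_na = pools$culm_na,
                      part = c(pl_s[d], pc_s[d], pp_s[d]), sla = sla_s[d],
                      retain_senescent_na =
                        isTRUE(modes$retain_senescent_na))
    state <- g$state
    pools$leaf_na_by_layer <- g$leaf_na
    pools$culm_na <- g$culm_na
    pools$dead_na <- pools$dead_na + g$na_died + g$na_culm_fixed

    uptake <- 0
    if (salt_enabled && env$na_ext > 0 && state$tr_act > 0) {
      up <- daily_na_uptake(state$tr_act, env$rh, env$na_ext, state$dvs,
                            params, aux,
                            literal_rrbf = isTRUE(modes$rrbf_literal))
      uptake <- up$uptake
      pools <- allocate_day(uptake, pools, state, params)
    }
    cum_uptake <- cum_uptake + uptake
    if (state$dvs >= 0.6 && state$dvs <= 1.1)
      fertility <- fertility * (1 - stress$sterility_f)

    if (!daily) next
    leaf_b <- sum(state$leaf_biomass_by_layer)
    leaf_mean <- if (leaf_b > 0)
      sum(pools$leaf_na_by_layer) / (leaf_b * 1000) else 0
    out[d, ] <- c(d, state$dvs, state$lai,
                  leaf_b + state$culm_biomass + state$panicle_biomass +
                    state$dead_leaf_biomass,
                  leaf_b, state$culm_biomass, state$panicle_biomass,
                  state$dead_leaf_biomass, state$tr_act, env$na_ext,
                  uptake, pools$culm_na, pools$panicle_na,
                  sum(pools$leaf_na_by_layer), pools$dead_na,
                  leaf_mean, g$carbon$rpn_eff,
                  stress$mresp_f, stress$sterility_f, stress$sla_stress,
                  stress$cvs_stress, g$carbon$gross, g$carbon$maint,
                  g$carbon$stress_loss)
  }

  balance_err <- if (cum_uptake > 0) {
    abs(total_na(pools) - cum_uptake) / cum_uptake
  } else {
    abs(total_na(pools))
  }
  structure(list(
    daily = if (daily) as.data.frame(out),
    yield = state$panicle_biomass * host$grain_fraction,
    agb = sum(state$leaf_biomass_by_layer) + state$culm_biomass +
      state$panicle_biomass + state$dead_leaf_biomass,
    cumulative_fertility = fertility,
    final_pools = pools,
    na_balance_error = balance_err
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  if (is.null(x$daily)) {
    cat("Season simulation (summaries only)\n")
  } else {
    cat("Season simulation:", nrow(x$daily), "days\n")
    cat(sprintf("  final DVS            %.2f\n",
                x$daily$dvs[nrow(x$daily)]))
  }
  cat(sprintf("  yield                %.0f kg/ha\n", x$yield))
  cat(sprintf("  aboveground biomass  %.0f kg/ha\n", x$agb))
  cat(sprintf("  cumulative fertility %.3f\n", x$cumulative_fertility))
  cat(sprintf("  plant Na+            %.1f g/ha\n",
              total_na(x$final_pools) / 1000))
  invisible(x)
}

#' Hydroponic (growth chamber) forcing
#'
#' Constant-condition forcing emulating a growth-chamber hydroponic
#' experiment: a 14 h / 10 h photoperiod with day/night temperatures
#' 26/18 C (daily mean 22.7 C used for thermal time), constant lamp
#' radiation, relative humidity cycling inside the 58-92% band, and a
#' constant NaCl treatment.
#'
#' @param days Length of the run (days).
#' @param na_mm NaCl treatment concentration (mM).
#' @param radiation Daily shortwave-equivalent radiation (MJ m-2 d-1).
#' @param et0 Reference evapotranspiration inside the chamber (mm d-1).
#' @param rh_band Relative-humidity band (%); the daily series cycles
#'   sinusoidally between the two bounds.
#' @return A list with `weather` (data frame) and `salinity` (mM vector),
#'   ready for [run_season()].
#' @export
hydroponic_forcing <- function(days = 120, na_mm = 0, radiation = 8.8,
                               et0 = 3, rh_band = c(58, 92)) {
  tmean <- (26 * 14 + 18 * 10) / 24
  rh_mid <- mean(rh_band)
  rh_amp <- diff(rh_band) / 2
  d <- seq_len(days)
  weather <- data.frame(
    day = d,
    tmean = rep(tmean, days),
    radiation = rep(radiation, days),
    rh = rh_mid + rh_amp * sin(2 * pi * d / 7),
    et0 = rep(et0, days)
  )
  list(weather = weather, salinity = rep(na_mm, days))
}
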