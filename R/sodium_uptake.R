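#' Relative apoplastic water flux as a function of air humidity
#'
#' Percentage of total water uptake that travels the apoplastic (bypass)
#' pathway into the root xylem. The share declines linearly with air
#' relative humidity, reflecting the lower transpirational pull of humid
#' air: `RJvB = -0.0275 * rh + 3.92`, floored at zero.
#'
#' @param rh Air relative humidity (%), in \[0, 100\].
#' @return Bypass share of water uptake (%).
#' @export
relative_bypass_water <- function(rh) {
  if (any(rh < 0 | rh > 100))
    stop("relative humidity must be within [0, 100] %", call. = FALSE)
  pmax(0, -0.0275 * rh + 3.92)
}

#' Water flux through the apoplastic pathway
#'
#' @param tr_act Actual transpiration (mm d-1), >= 0.
#' @param rjv_b Bypass share of water uptake (%), e.g. from
#'   [relative_bypass_water()].
#' @return Apoplastic water flux (mm d-1).
#' @export
bypass_water_flux <- function(tr_act, rjv_b) {
  if (any(tr_act < 0))
    stop("transpiration must be >= 0", call. = FALSE)
  tr_act * rjv_b / 100
}

#' Suberin deposition response to external salinity
#'
#' Dimensionless driver of salinity-induced suberin deposition. It rises
#' with the external Na+ concentration, faster for genotypes with a higher
#' deposition efficiency, and saturates at 1:
#' `F_sc = (na_ext / max_na_ext) / (1 - sub_dep_eff)`, clamped to \[0, 1\]
#' (the unclamped expression exceeds 1 as `na_ext` approaches `max_na_ext`
#' whenever `sub_dep_eff > 0`).
#'
#' @param na_ext External Na+ concentration (mM), >= 0.
#' @param max_na_ext Na+ concentration at which deposition saturates (mM).
#' @param sub_dep_eff Suberin deposition efficiency (fraction in \[0, 1)).
#' @return Deposition response (fraction, 0-1).
#' @export
suberin_deposition_response <- function(na_ext, max_na_ext, sub_dep_eff) {
  if (max_na_ext <= 0) stop("'max_na_ext' must be > 0", call. = FALSE)
  if (any(sub_dep_eff >= 1))
    stop("'sub_dep_eff' = 1 makes the deposition response singular",
         call. = FALSE)
  if (any(na_ext < 0)) stop("'na_ext' must be >= 0", call. = FALSE)
  clamp((na_ext / max_na_ext) / (1 - sub_dep_eff), 0, 1)
}

#' Root suberin content
#'
#' Saturating function of plant developmental stage and of the
#' salinity-induced deposition response:
#' `SC = sc_max * dvs * (0.5 * (1 - f_sc) + 1) / ((1 - f_sc) + dvs)`.
#' At emergence (`dvs = 0`) the content is zero; it rises with age and with
#' `f_sc`, never exceeding `sc_max`. The indeterminate corner
#' `dvs = 0, f_sc = 1` is resolved to 0 (its directional limit along age).
#'
#' @param dvs Development stage (unitless, 0 = emergence, 1 = anthesis,
#'   2 = maturity).
#' @param f_sc Deposition response (fraction, 0-1), from
#'   [suberin_deposition_response()].
#' @param sc_max Maximum suberin content (mg g-1).
#' @return Root suberin content (mg g-1), in \[0, sc_max\].
#' @export
suberin_content <- function(dvs, f_sc, sc_max) {
  if (any(dvs < 0 | dvs > 2))
    stop("'dvs' must be within [0, 2]", call. = FALSE)
  denom <- (1 - f_sc) + dvs
  ifelse(denom <= 0, 0,
         sc_max * dvs * (0.5 * (1 - f_sc) + 1) / denom)
}

#' Relative bypass flow as a function of suberin content
#'
#' Fraction of the potential apoplastic flux that remains open given the
#' current root suberin content. In the default (canonical) form,
#' `RRBF = (rrbf_min / 100) ^ ((sc - sc_min) / (sc_max - sc_min))`:
#' an unsuberized root (`sc = sc_min`) leaves the pathway fully open
#' (RRBF = 1) and a maximally suberized root reduces it to `rrbf_min`
#' percent, decreasing monotonically in between. `literal_mode = TRUE`
#' instead evaluates the alternative published arrangement
#' `RRBF = (1/100) * rrbf_min ^ fraction`, which increases with suberin
#' content from 0.01 to `rrbf_min / 100`; it is retained for auditability
#' only (see the methods vignette).
#'
#' Inputs outside `[sc_min, sc_max]` are clamped to that interval.
#'
#' @param sc Root suberin content (mg g-1).
#' @param params A [trait_parameters()] object (uses `rrbf_min`, `sc_max`).
#' @param aux An [auxiliary_constants()] object (uses `sc_min`).
#' @param literal_mode Evaluate the as-published arrangement instead of the
#'   canonical monotone-decreasing form. Default `FALSE`.
#' @return Relative bypass flow (fraction in (0, 1\]).
#' @export
relative_bypass_flow <- function(sc, params, aux = auxiliary_constants(),
                                 literal_mode = FALSE) {
  if (params$sc_max <= aux$sc_min)
    stop("'sc_max' must exceed 'sc_min'", call. = FALSE)
  frac <- (clamp(sc, aux$sc_min, params$sc_max) - aux$sc_min) /
    (params$sc_max - aux$sc_min)
  if (literal_mode) {
    (1 / 100) * params$rrbf_min^frac
  } else {
    (params$rrbf_min / 100)^frac
  }
}

# grams of Na+ per mole; converts mM (mmol L-1) to mg L-1
.NA_MOLAR_MASS <- 22.98977

#' Shoot Na+ uptake through the bypass-flow pathway
#'
#' Mass of Na+ delivered daily to the shoot by the apoplastic water flux:
#' `uptake = jv_b * 1e4 * rrbf * na_ext * 22.99` (mg ha-1), where
#' 1e4 L ha-1 mm-1 converts the water depth to a volume per hectare and
#' 22.99 mg L-1 mM-1 is the mass concentration of Na+ per unit molarity.
#'
#' @param jv_b Apoplastic water flux (mm d-1), >= 0.
#' @param rrbf Relative bypass flow (fraction), >= 0.
#' @param na_ext External Na+ concentration (mM), >= 0.
#' @return Apoplastic Na+ uptake (mg ha-1 d-1).
#' @export
apoplastic_na_uptake <- function(jv_b, rrbf, na_ext) {
  if (any(jv_b < 0 | rrbf < 0 | na_ext < 0))
    stop("all inputs must be >= 0", call. = FALSE)
  jv_b * 1e4 * rrbf * na_ext * .NA_MOLAR_MASS
}

#' Bypass share of total shoot Na+ uptake
#'
#' Percentage of the total shoot Na+ uptake carried by the bypass pathway,
#' modelled (like the water-flux share) as a linear function of relative
#' humidity. The default coefficients map the 58-92% humidity band onto the
#' 35-22% bypass share reported for rice.
#'
#' @param rh Air relative humidity (%).
#' @param aux An [auxiliary_constants()] object supplying the linear
#'   coefficients.
#' @return Bypass share of total Na+ uptake (%), must be positive.
#' @export
relative_na_uptake_ap <- function(rh, aux = auxiliary_constants()) {
  share <- aux$rna_uptake_slope * rh + aux$rna_uptake_intercept
  if (any(share <= 0))
    stop("configured bypass-share relation gives a non-positive share",
         call. = FALSE)
  share
}

#' Total daily shoot Na+ uptake
#'
#' Scales the apoplastic uptake up to the total (apoplastic plus
#' transmembrane) shoot uptake: `total = uptake_ap * 100 / share`.
#'
#' @param uptake_ap Apoplastic Na+ uptake (mg ha-1 d-1), >= 0.
#' @param rna_uptake_ap Bypass share of total uptake (%), > 0; typically
#'   from [relative_na_uptake_ap()].
#' @return Total shoot Na+ uptake (mg ha-1 d-1).
#' @export
total_na_uptake <- function(uptake_ap, rna_uptake_ap) {
  if (any(uptake_ap < 0))
    stop("'uptake_ap' must be >= 0", call. = FALSE)
  if (any(rna_uptake_ap <= 0))
    stop("'rna_uptake_ap' must be > 0", call. = FALSE)
  uptake_ap * 100 / rna_uptake_ap
}

#' One day of shoot Na+ uptake, chained
#'
#' Convenience wrapper running the whole uptake chain for one day:
#' humidity-driven bypass water share, apoplastic flux, salinity-driven
#' suberin deposition, suberin content, relative bypass flow, apoplastic
#' uptake, and scaling to total shoot uptake.
#'
#' @param tr_act Actual transpiration (mm d-1).
#' @param rh Air relative humidity (%).
#' @param na_ext External Na+ concentration (mM).
#' @param dvs Development stage (0-2).
#' @param params A [trait_parameters()] object.
#' @param aux An [auxiliary_constants()] object.
#' @param literal_rrbf Use the as-published bypass-flow arrangement.
#' @return A list with components `rjv_b`, `jv_b`, `f_sc`, `sc`, `rrbf`,
#'   `uptake_ap`, `uptake` (all scalar).
#' @export
daily_na_uptake <- function(tr_act, rh, na_ext, dvs, params,
                            aux = auxiliary_constants(),
                            literal_rrbf = FALSE) {
  rjv_b <- relative_bypass_water(rh)
  jv_b <- bypass_water_flux(tr_act, rjv_b)
  f_sc <- suberin_deposition_response(na_ext, aux$max_na_ext,
                                      params$sub_dep_eff)
  sc <- suberin_content(dvs, f_sc, params$sc_max)
  rrbf <- relative_bypass_flow(sc, params, aux, literal_mode = literal_rrbf)
  uptake_ap <- apoplastic_na_uptake(jv_b, rrbf, na_ext)
  uptake <- total_na_uptake(uptake_ap, relative_na_uptake_ap(rh, aux))
  list(rjv_b = rjv_b, jv_b = jv_b, f_sc = f_sc, sc = sc, rrbf = rrbf,
       uptake_ap = uptake_ap, uptake = uptake)
}
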