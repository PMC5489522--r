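#' Trait parameters of the salt-tolerance model
#'
#' Constructs the set of ten genotype-specific parameters that represent the
#' five physiological salt-tolerance traits of rice targeted by breeding
#' programmes: (T1) reduction of shoot Na+ uptake via suberin-mediated
#' restriction of the apoplastic bypass flow, (T2) Na+ sequestration into
#' structural culm tissue, (T3) tolerance to salt-induced spikelet sterility,
#' (T4) compartmentation of Na+ into the oldest (senescing) leaves, and
#' (T5) leaf tissue tolerance. Defaults are the distribution means used for
#' the sensitivity analysis.
#'
#' @param rrbf_min Bypass flow when root suberin content is maximum (%),
#'   in (0, 100].
#' @param sub_dep_eff Suberin deposition efficiency (unitless, 0-1).
#' @param sc_max Maximum root suberin content (mg g-1).
#' @param pot_c_seq Potential culm Na+ sequestration rate (mg plant-1 d-1).
#' @param na_culm_max Maximum culm Na+ concentration (mg g-1).
#' @param susc_st Susceptibility to salt-induced sterility (unitless).
#' @param na_to_pan Na+ translocation factor to panicles (unitless, 0-1).
#' @param part_cap Capability of partitioning Na+ to the oldest leaves
#'   (unitless, 0-1).
#' @param thresh_l Leaf Na+ concentration above which photosynthesis is
#'   reduced (mg g-1).
#' @param crit_l Leaf Na+ concentration at which photosynthesis becomes null
#'   (mg g-1); must exceed `thresh_l`.
#'
#' @return An object of class `trait_parameters` (a validated named list).
#' @examples
#' tp <- trait_parameters()
#' tp$rrbf_min
#' @export
trait_parameters <- function(rrbf_min = 5,
                             sub_dep_eff = 0.62,
                             sc_max = 30,
                             pot_c_seq = 0.029,
                             na_culm_max = 26,
                             susc_st = 0.00135,
                             na_to_pan = 0.2,
                             part_cap = 0.7,
                             thresh_l = 1.5,
                             crit_l = 35) {
  p <- list(
    rrbf_min = rrbf_min, sub_dep_eff = sub_dep_eff, sc_max = sc_max,
    pot_c_seq = pot_c_seq, na_culm_max = na_culm_max, susc_st = susc_st,
    na_to_pan = na_to_pan, part_cap = part_cap, thresh_l = thresh_l,
    crit_l = crit_l
  )
  validate_trait_parameters(p)
  structure(p, class = "trait_parameters")
}

validate_trait_parameters <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("trait parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  if (any(unlist(p) < 0))
    stop("trait parameters must all be non-negative", call. = FALSE)
  if (p$rrbf_min <= 0 || p$rrbf_min > 100)
    stop("'rrbf_min' must be in (0, 100] (percent)", call. = FALSE)
  for (nm in c("sub_dep_eff", "na_to_pan", "part_cap")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("'", nm, "' must be a fraction in [0, 1]", call. = FALSE)
  }
  if (p$crit_l <= p$thresh_l)
    stop("'crit_l' must exceed 'thresh_l'", call. = FALSE)
  invisible(p)
}

#' Auxiliary (non-trait) constants of the salinity module
#'
#' Constants that shape the salinity response but are not themselves breeding
#' targets. `sc_min` is the minimum root suberin content at which the bypass
#' flow starts to be reduced; `max_na_ext` is the external Na+ concentration
#' at which suberin deposition saturates (default 300 mM, near-seawater
#' salinity: with the default deposition efficiency the response then
#' saturates at about 114 mM, so deposition keeps responding across the
#' whole 0-50 mM experimental range and root barriers stay age-limited
#' early in the season); `na_leaf_min` is the Na+
#' concentration of
#' unstressed leaves; `shape_c` shapes the leaf photosynthesis response
#' curve; `na_resp_thresh` and `na_resp_crit` bound the linear ramp of the
#' maintenance-respiration factor (respiration doubles at `na_resp_crit`).
#' `rna_uptake_slope`/`rna_uptake_intercept` define the linear dependence of
#' the bypass share of total Na+ uptake (%) on air relative humidity; the
#' defaults map the 58-92% humidity band onto the 35-22% bypass share
#' reported for rice.
#'
#' @param sc_min Minimum suberin content (mg g-1), below `sc_max`.
#' @param max_na_ext Saturating external Na+ concentration (mM), > 0.
#' @param na_leaf_min Unstressed leaf Na+ concentration (mg g-1).
#' @param shape_c Shape coefficient of the photosynthesis response (> 0).
#' @param na_resp_thresh Leaf Na+ concentration at which maintenance
#'   respiration starts to rise (mg g-1).
#' @param na_resp_crit Leaf Na+ concentration at which maintenance
#'   respiration is doubled (mg g-1), > `na_resp_thresh`.
#' @param rna_uptake_slope,rna_uptake_intercept Coefficients of the linear
#'   relation bypass-share(%) = slope * RH + intercept.
#'
#' @return An object of class `auxiliary_constants`.
#' @export
auxiliary_constants <- function(sc_min = 0,
                                max_na_ext = 300,
                                na_leaf_min = 0,
                                shape_c = 1,
                                na_resp_thresh = 0.5,
                                na_resp_crit = 3,
                                rna_uptake_slope = -13 / 34,
                                rna_uptake_intercept = 35 + 58 * 13 / 34) {
  a <- list(
    sc_min = sc_min, max_na_ext = max_na_ext, na_leaf_min = na_leaf_min,
    shape_c = shape_c, na_resp_thresh = na_resp_thresh,
    na_resp_crit = na_resp_crit, rna_uptake_slope = rna_uptake_slope,
    rna_uptake_intercept = rna_uptake_intercept
  )
  if (a$max_na_ext <= 0)
    stop("'max_na_ext' must be > 0", call. = FALSE)
  if (a$na_resp_crit <= a$na_resp_thresh)
    stop("'na_resp_crit' must exceed 'na_resp_thresh'", call. = FALSE)
  if (a$shape_c <= 0) stop("'shape_c' must be > 0", call. = FALSE)
  structure(a, class = "auxiliary_constants")
}

#' One day of environmental forcing
#'
#' @param tmean Mean air temperature (degrees C).
#' @param radiation Global solar radiation (MJ m-2 d-1).
#' @param rh Air relative humidity (%), in \[0, 100\].
#' @param et0 Reference evapotranspiration (mm d-1).
#' @param na_ext Na+ concentration of the external medium (mM), >= 0.
#'
#' @return An object of class `daily_environment`.
#' @export
daily_environment <- function(tmean, radiation, rh, et0, na_ext = 0) {
  if (rh < 0 || rh > 100)
    stop("relative humidity must be within [0, 100] %", call. = FALSE)
  if (na_ext < 0)
    stop("external Na+ concentration must be >= 0", call. = FALSE)
  if (radiation < 0 || et0 < 0)
    stop("radiation and et0 must be >= 0", call. = FALSE)
  structure(list(tmean = tmean, radiation = radiation, rh = rh,
                 et0 = et0, na_ext = na_ext),
            class = "daily_environment")
}

#' @export
print.trait_parameters <- function(x, ...) {
  cat("Salt-tolerance trait parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

clamp <- function(x, lo, hi) {
  if (length(x) == 1L) {
    if (x < lo) lo else if (x > hi) hi else x
  } else {
    pmin(pmax(x, lo), hi)
  }
}
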