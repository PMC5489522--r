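#' Photosynthesis stress factor from leaf Na+ concentration
#'
#' Multiplier (0-1) applied to gross photosynthesis of a leaf layer, also
#' used to accelerate its senescence. In the canonical form the response is
#' the classic beta-type response curve: 1 for concentrations up to
#' `thresh_l`, 0 at and above `crit_l`, and strictly decreasing in between,
#' \deqn{RPn = \left[\frac{x - x_{min}}{t - x_{min}} \cdot \left(\frac{c - x}{c - t}\right)^{\frac{c - t}{t - x_{min}}}\right]^{C}}{
#' RPn = [ ((x - xmin)/(t - xmin)) * ((c - x)/(c - t))^((c - t)/(t - xmin)) ]^C}
#' with `x` the leaf concentration, `t = thresh_l`, `c = crit_l`,
#' `xmin = na_leaf_min`: the standard beta-function placement, whose
#' stationary maximum of 1 sits exactly at the threshold.
#' `literal_mode = TRUE` evaluates the alternative arrangement that raises
#' the whole two-factor product to the exponent
#' `((c - t)/(t - xmin))^C`; that expression exceeds 1 and explodes inside
#' the (t, c) interval and is retained for auditability only.
#'
#' @param na_leaf Leaf Na+ concentration (mg g-1), scalar or vector.
#' @param thresh_l Concentration above which stress starts (mg g-1).
#' @param crit_l Concentration at which photosynthesis is null (mg g-1).
#' @param na_leaf_min Concentration of unstressed leaves (mg g-1).
#' @param shape_c Shape coefficient (> 0), default 1.
#' @param literal_mode Evaluate the as-published arrangement.
#' @return Stress factor(s) in \[0, 1\] (canonical mode).
#' @export
photosynthesis_stress <- function(na_leaf, thresh_l, crit_l,
                                  na_leaf_min = 0, shape_c = 1,
                                  literal_mode = FALSE) {
  if (!(na_leaf_min < thresh_l && thresh_l < crit_l))
    stop("require na_leaf_min < thresh_l < crit_l", call. = FALSE)
  if (literal_mode) {
    f1 <- pmax(0, (na_leaf - na_leaf_min) / (thresh_l - na_leaf_min))
    f2 <- pmax(0, (crit_l - na_leaf) / (crit_l - thresh_l))
    return((f1 * f2)^(((crit_l - thresh_l) / (thresh_l - na_leaf_min))^shape_c))
  }
  expo <- (crit_l - thresh_l) / (thresh_l - na_leaf_min)
  x <- clamp(na_leaf, thresh_l, crit_l)
  f1 <- (x - na_leaf_min) / (thresh_l - na_leaf_min)
  f2 <- ((crit_l - x) / (crit_l - thresh_l))^expo
  clamp((f1 * f2)^shape_c, 0, 1)
}

#' Maintenance-respiration increase factor
#'
#' Linear ramp in the biomass-weighted mean leaf Na+ concentration, from 0
#' at `na_resp_thresh` (default 0.5 mg g-1) to 1 at `na_resp_crit`
#' (default 3 mg g-1, where maintenance respiration is doubled); the host
#' multiplies leaf and culm maintenance respiration by `1 + MRespF`.
#'
#' @param na_leaves_mean Mean leaf Na+ concentration (mg g-1), weighted by
#'   layer biomass.
#' @param aux An [auxiliary_constants()] object.
#' @return Respiration increase factor (fraction, 0-1).
#' @export
respiration_factor <- function(na_leaves_mean, aux = auxiliary_constants()) {
  clamp((na_leaves_mean - aux$na_resp_thresh) /
          (aux$na_resp_crit - aux$na_resp_thresh), 0, 1)
}

#' Phenological susceptibility window for salt-induced sterility
#'
#' Bell-shaped modulation of sterility susceptibility, maximal at the two
#' most sensitive stages: booting (microsporogenesis, DVS = 0.8) and
#' flowering (DVS = 1.0). Implemented as the maximum of two Gaussian bells,
#' zeroed outside the sensitive window \[0.6, 1.1\].
#'
#' @param dvs Development stage (0-2).
#' @param centers DVS of maximum susceptibility (default booting 0.8 and
#'   flowering 1.0).
#' @param sigma Width of each bell (DVS units, default 0.05).
#' @param window DVS interval outside which susceptibility is zero.
#' @return Susceptibility modifier (0-1).
#' @export
sterility_bell <- function(dvs, centers = c(0.8, 1.0), sigma = 0.05,
                           window = c(0.6, 1.1)) {
  b <- exp(-0.5 * ((dvs - centers[1]) / sigma)^2)
  for (mu in centers[-1])
    b <- pmax(b, exp(-0.5 * ((dvs - mu) / sigma)^2))
  ifelse(dvs >= window[1] & dvs <= window[2], b, 0)
}

#' Spikelet sterility factor
#'
#' Daily reduction of spikelet fertility driven by the panicle Na+
#' concentration: `susc_st * conc * bellF` within 0.6 <= DVS <= 1.1 and 0
#' elsewhere, clamped to \[0, 1\]. The host multiplies the daily
#' photosynthate flux to panicles by `1 - SterilityF`.
#'
#' @param na_panicle_conc Panicle Na+ concentration (mg g-1), >= 0.
#' @param susc_st Genotype susceptibility (unitless).
#' @param dvs Development stage (0-2).
#' @param bell_params Optional list overriding `centers`, `sigma`, `window`
#'   of [sterility_bell()].
#' @return Sterility factor (fraction, 0-1).
#' @export
sterility_factor <- function(na_panicle_conc, susc_st, dvs,
                             bell_params = list()) {
  if (any(na_panicle_conc < 0))
    stop("panicle concentration must be >= 0", call. = FALSE)
  bell <- do.call(sterility_bell, c(list(dvs = dvs), bell_params))
  clamp(susc_st * na_panicle_conc * bell, 0, 1)
}

#' Osmotic stress factor on specific leaf area
#'
#' Quadratic response of leaf-area expansion to the osmotic potential of
#' the external medium: `-0.0002 * na^2 + 0.008 * na + 1`. The raw
#' quadratic exceeds 1 for mild salinity (0-40 mM); because the factor is
#' defined as a 0-1 reduction factor, the default clamps it to \[0, 1\]
#' (`clamp = FALSE` returns the raw quadratic, floored at 0).
#'
#' @param na_ext External Na+ concentration (mM), >= 0.
#' @param clamp_at_one Clamp the factor at 1 (default TRUE).
#' @return SLA stress factor (unitless).
#' @export
osmotic_sla_factor <- function(na_ext, clamp_at_one = TRUE) {
  if (any(na_ext < 0)) stop("'na_ext' must be >= 0", call. = FALSE)
  f <- pmax(0, -0.0002 * na_ext^2 + 0.008 * na_ext + 1)
  if (clamp_at_one) pmin(f, 1) else f
}

#' Osmotic stress factor on culm growth
#'
#' Quadratic reduction of culm expansion by external osmotic stress:
#' `0.0002 * na^2 - 0.024 * na + 1`, clamped to \[0, 1\].
#'
#' @param na_ext External Na+ concentration (mM), >= 0.
#' @return Culm growth stress factor (unitless, 0-1).
#' @export
osmotic_culm_factor <- function(na_ext) {
  if (any(na_ext < 0)) stop("'na_ext' must be >= 0", call. = FALSE)
  clamp(0.0002 * na_ext^2 - 0.024 * na_ext + 1, 0, 1)
}

#' Compute the full set of stress factors for one day
#'
#' @param pools A [sodium_pools()] object.
#' @param state A [crop_state()] object.
#' @param na_ext External Na+ concentration (mM).
#' @param params A [trait_parameters()] object.
#' @param aux An [auxiliary_constants()] object.
#' @param modes List of equation-mode switches (`rpn_literal`,
#'   `sla_clamp`), see [default_modes()].
#' @return A list of class `stress_factors` with `rpn_by_layer`, `mresp_f`,
#'   `sterility_f`, `sla_stress`, `cvs_stress`.
#' @export
stress_factors <- function(pools, state, na_ext, params,
                           aux = auxiliary_constants(),
                           modes = default_modes()) {
  conc <- na_concentrations(pools, state)
  rpn <- photosynthesis_stress(conc$leaf_by_layer, params$thresh_l,
                               params$crit_l, aux$na_leaf_min, aux$shape_c,
                               literal_mode = isTRUE(modes$rpn_literal))
  bp <- modes$bell_params %||% list()
  structure(list(
    rpn_by_layer = rpn,
    mresp_f = respiration_factor(conc$leaf_mean, aux),
    sterility_f = if (length(bp)) {
      sterility_factor(conc$panicle, params$susc_st, state$dvs, bp)
    } else {
      clamp(params$susc_st * conc$panicle * sterility_bell(state$dvs),
            0, 1)
    },
    sla_stress = osmotic_sla_factor(na_ext,
                                    clamp_at_one = !isFALSE(modes$sla_clamp)),
    cvs_stress = osmotic_culm_factor(na_ext)
  ), class = "stress_factors")
}

#' Neutral (no-stress) factors
#' @param n_layers Number of canopy layers.
#' @return A `stress_factors` object that leaves the host unchanged.
#' @export
neutral_stress <- function(n_layers = 5) {
  structure(list(rpn_by_layer = rep(1, n_layers), mresp_f = 0,
                 sterility_f = 0, sla_stress = 1, cvs_stress = 1),
            class = "stress_factors")
}

#' Equation-mode switches
#'
#' Central place for the switches selecting between canonical and
#' as-published arrangements of ambiguous response curves, and for the
#' sterility bell parameters.
#'
#' @param rrbf_literal Use the as-published bypass-flow arrangement.
#' @param rpn_literal Use the as-published photosynthesis response.
#' @param sla_clamp Clamp the SLA osmotic factor at 1.
#' @param k_sen Senescence amplification coefficient: the relative death
#'   rate of a layer is multiplied by `1 + k_sen * (1 - RPn)`.
#' @param retain_senescent_na Keep the Na+ of dying leaf tissue in its
#'   layer instead of moving it to the dead-tissue ledger.
#' @param bell_params Parameters passed to [sterility_bell()].
#' @return A named list.
#' @export
default_modes <- function(rrbf_literal = FALSE, rpn_literal = FALSE,
                          sla_clamp = TRUE, k_sen = 1,
                          retain_senescent_na = FALSE,
                          bell_params = list()) {
  list(rrbf_literal = rrbf_literal, rpn_literal = rpn_literal,
       sla_clamp = sla_clamp, k_sen = k_sen,
       retain_senescent_na = retain_senescent_na,
       bell_params = bell_params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
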