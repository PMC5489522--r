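#' Sodium pools of the shoot
#'
#' Container for the cumulative Na+ mass stored in the culm, the panicle,
#' each living leaf layer (index 1 = bottom = oldest), and tissue that has
#' already senesced. All pools are in mg ha-1.
#'
#' @param n_layers Number of living canopy layers.
#' @param culm_na,panicle_na,dead_na Initial pool masses (mg ha-1).
#' @param leaf_na_by_layer Initial per-layer leaf pools (mg ha-1), bottom
#'   first; defaults to zeros.
#' @return An object of class `sodium_pools`.
#' @export
sodium_pools <- function(n_layers = 5, culm_na = 0, panicle_na = 0,
                         dead_na = 0,
                         leaf_na_by_layer = rep(0, n_layers)) {
  if (length(leaf_na_by_layer) != n_layers)
    stop("'leaf_na_by_layer' must have one entry per layer", call. = FALSE)
  if (culm_na < 0 || panicle_na < 0 || dead_na < 0 ||
      any(leaf_na_by_layer < 0))
    stop("sodium pools must be non-negative", call. = FALSE)
  structure(list(culm_na = culm_na, panicle_na = panicle_na,
                 dead_na = dead_na,
                 leaf_na_by_layer = as.numeric(leaf_na_by_layer)),
            class = "sodium_pools")
}

#' Total Na+ mass across all shoot compartments
#'
#' @param pools A [sodium_pools()] object.
#' @return Total Na+ (mg ha-1), including the dead-tissue ledger.
#' @export
total_na <- function(pools) {
  pools$culm_na + pools$panicle_na + pools$dead_na +
    sum(pools$leaf_na_by_layer)
}

#' Relative Na+ sink size of the culm
#'
#' Remaining fraction of the culm's storage capacity:
#' `1 - conc / na_culm_max`, clamped to \[0, 1\].
#'
#' @param culm_na_conc Actual culm Na+ concentration (mg g-1).
#' @param na_culm_max Maximum culm Na+ concentration (mg g-1), > 0.
#' @return Relative sink size (fraction, 0-1).
#' @export
relative_sink_size <- function(culm_na_conc, na_culm_max) {
  if (na_culm_max <= 0)
    stop("'na_culm_max' must be > 0", call. = FALSE)
  if (any(culm_na_conc < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  clamp(1 - culm_na_conc / na_culm_max, 0, 1)
}

#' Actual culm Na+ sequestration rate
#'
#' Potential genotypic sequestration scaled per hectare and damped by a
#' feedback on the Na+ already stored:
#' `rate = pot_c_seq * density * (1 - 0.08 * ((rel_sink + 0.1)^-1.13 - 0.08))`.
#' The feedback term exceeds 1 for small `rel_sink`, so the rate is floored
#' at zero: a saturated sink sequesters nothing.
#'
#' @param rel_sink Relative sink size (fraction, 0-1).
#' @param pot_c_seq Potential sequestration rate (mg plant-1 d-1).
#' @param density Plant density (plants ha-1).
#' @return Sequestration rate (mg ha-1 d-1), >= 0.
#' @export
culm_sequestration_rate <- function(rel_sink, pot_c_seq, density) {
  if (any(rel_sink < 0 | rel_sink > 1))
    stop("'rel_sink' must be in [0, 1]", call. = FALSE)
  feedback <- 1 - 0.08 * ((rel_sink + 0.1)^-1.13 - 0.08)
  pmax(0, pot_c_seq * density * feedback)
}

#' Daily Na+ delivery to the panicle
#'
#' Na+ not sequestered in culms is partly carried to the panicle with the
#' photosynthate stream, but only once panicles are a sink
#' (0.6 <= DVS <= 2): `par_p * na_to_pan * max(0, uptake - culm_seq)`.
#'
#' @param na_uptake Total daily shoot Na+ uptake (mg ha-1).
#' @param culm_seq Na+ sequestered in culms today (mg ha-1).
#' @param par_p Fraction of photosynthates partitioned to panicles (0-1).
#' @param na_to_pan Na+ translocation factor to panicles (0-1).
#' @param dvs Development stage (0-2).
#' @return Na+ delivered to panicles (mg ha-1 d-1).
#' @export
panicle_na_delivery <- function(na_uptake, culm_seq, par_p, na_to_pan, dvs) {
  surplus <- pmax(0, na_uptake - culm_seq)
  ifelse(dvs >= 0.6 & dvs <= 2, par_p * na_to_pan * surplus, 0)
}

#' Partition of leaf-bound Na+ across canopy layers
#'
#' Plants protect photosynthetically active tissue by routing Na+
#' preferentially to the oldest leaves. Layer i (1 = bottom = oldest)
#' receives the weight `(1 - part_cap)^((i - 1) / (N - 1))`, normalized over
#' the N living layers, so weights decay geometrically from bottom to top;
#' `part_cap = 0` splits equally and the single-layer case receives
#' everything. `part_cap = 1` with N > 1 is handled as its limit: all Na+
#' to the bottom layer.
#'
#' @param na_leaves Na+ reaching leaves today (mg ha-1).
#' @param part_cap Partitioning capability to old leaves (fraction, 0-1).
#' @param n_layers Number of living layers (N >= 1).
#' @return Numeric vector of per-layer deliveries (mg ha-1), bottom first,
#'   summing to `na_leaves`.
#' @export
leaf_layer_partition <- function(na_leaves, part_cap, n_layers) {
  if (n_layers < 1) stop("'n_layers' must be >= 1", call. = FALSE)
  if (part_cap < 0 || part_cap > 1)
    stop("'part_cap' must be in [0, 1]", call. = FALSE)
  if (n_layers == 1) return(na_leaves)
  if (part_cap == 1) return(c(na_leaves, rep(0, n_layers - 1)))
  w <- (1 - part_cap)^((seq_len(n_layers) - 1) / (n_layers - 1))
  na_leaves * w / sum(w)
}

#' Allocate one day's Na+ uptake among shoot compartments
#'
#' Distributes the total daily shoot Na+ uptake among culm storage, the
#' panicle, and leaf layers. Culm sequestration follows the feedback rule,
#' additionally capped by the uptake itself and by the culm's remaining
#' concentration headroom (`na_culm_max`). The panicle takes its share of
#' the surplus during 0.6 <= DVS <= 2, and the exact residual reaches the
#' leaves, split by layer age. Mass is conserved to machine precision.
#'
#' @param uptake Total daily shoot Na+ uptake (mg ha-1), >= 0.
#' @param pools A [sodium_pools()] object.
#' @param state A [crop_state()] object (uses dvs, par_p, plant_density,
#'   culm biomass, layer count).
#' @param params A [trait_parameters()] object.
#' @return The updated `sodium_pools` object.
#' @export
allocate_day <- function(uptake, pools, state, params) {
  if (uptake < 0) stop("'uptake' must be >= 0", call. = FALSE)
  n <- state$n_layers
  culm_g <- state$culm_biomass * 1000          # kg ha-1 -> g ha-1
  conc <- if (culm_g > 0) pools$culm_na / culm_g else params$na_culm_max
  rel_sink <- relative_sink_size(conc, params$na_culm_max)
  seq_rate <- culm_sequestration_rate(rel_sink, params$pot_c_seq,
                                      state$plant_density)
  headroom <- max(0, params$na_culm_max * culm_g - pools$culm_na)
  culm_seq <- min(seq_rate, uptake, headroom)
  pan <- panicle_na_delivery(uptake, culm_seq, state$par_p,
                             params$na_to_pan, state$dvs)
  na_leaves <- uptake - culm_seq - pan
  if (na_leaves < -1e-9 * max(uptake, 1))
    stop("internal error: negative leaf Na+ residual", call. = FALSE)
  na_leaves <- max(0, na_leaves)
  layers <- leaf_layer_partition(na_leaves, params$part_cap, n)
  pools$culm_na <- pools$culm_na + culm_seq
  pools$panicle_na <- pools$panicle_na + pan
  pools$leaf_na_by_layer <- pools$leaf_na_by_layer + layers
  pools
}

#' Tissue Na+ concentrations from pools and organ biomasses
#'
#' @param pools A [sodium_pools()] object.
#' @param state A [crop_state()] object.
#' @return A list with `culm` (mg g-1), `panicle` (mg g-1), `leaf_by_layer`
#'   (mg g-1, bottom first) and `leaf_mean` (biomass-weighted mean over
#'   living layers, mg g-1).
#' @export
na_concentrations <- function(pools, state) {
  conc_of <- function(na_mg, kg) if (kg > 0) na_mg / (kg * 1000) else 0
  leaf_kg <- state$leaf_biomass_by_layer
  leaf_conc <- numeric(length(leaf_kg))
  pos <- leaf_kg > 0
  leaf_conc[pos] <- pools$leaf_na_by_layer[pos] / (leaf_kg[pos] * 1000)
  total_leaf <- sum(leaf_kg)
  list(
    culm = conc_of(pools$culm_na, state$culm_biomass),
    panicle = conc_of(pools$panicle_na, state$panicle_biomass),
    leaf_by_layer = leaf_conc,
    leaf_mean = if (total_leaf > 0)
      sum(pools$leaf_na_by_layer) / (total_leaf * 1000) else 0
  )
}
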