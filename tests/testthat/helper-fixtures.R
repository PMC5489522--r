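# Small shared fixtures; everything is generated in code.

default_tp <- trait_parameters()
default_ax <- auxiliary_constants()

short_weather <- function(days = 40, seed = 11) make_weather(days, seed)

# a mid-season crop state with round numbers, convenient for hand-traced
# allocation arithmetic
mid_state <- function(n_layers = 5) {
  st <- crop_state(host_parameters(n_layers = n_layers))
  st$dvs <- 1
  st$par_p <- 0.5
  st$leaf_biomass_by_layer <- rep(600, n_layers)   # 3000 kg/ha leaves
  st$culm_biomass <- 4000
  st$panicle_biomass <- 1000
  st$lai <- 4
  st$tr_act <- 4
  st
}
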