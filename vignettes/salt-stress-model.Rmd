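---
title: "A trait-based model of salt stress in rice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A trait-based model of salt stress in rice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltrice)
```

## Why a trait-based salinity model

Most crop models represent salt stress through a few empirical parameters
that map soil salinity directly onto yield or growth reduction. Those
parameters have no counterpart among the physiological traits rice
breeders actually select for, so such models cannot say *which* tolerance
mechanism a breeding programme should target in a given district.
`saltrice` instead builds the salinity response explicitly around five
breeding traits, each represented by named parameters of the model:

| Trait | Mechanism | Parameters (defaults) |
|-------|-----------|----------------------|
| T1 | Reduction of shoot Na⁺ uptake via suberin-limited bypass flow | `rrbf_min` (5%), `sub_dep_eff` (0.62), `sc_max` (30 mg g⁻¹) |
| T2 | Sequestration of Na⁺ into structural culm tissue | `pot_c_seq` (0.029 mg plant⁻¹ d⁻¹), `na_culm_max` (26 mg g⁻¹) |
| T3 | Tolerance to salt-induced spikelet sterility | `susc_st` (0.00135), `na_to_pan` (0.2) |
| T4 | Compartmentation of Na⁺ into the oldest leaves | `part_cap` (0.7) |
| T5 | Leaf tissue tolerance | `thresh_l` (1.5 mg g⁻¹), `crit_l` (35 mg g⁻¹) |

A genotype *is* its vector of ten trait parameters; everything else is
host-crop plumbing or fixed auxiliary constants.

## The daily salinity loop

Each simulated day proceeds through four stages.

**1. Shoot Na⁺ uptake.** Na⁺ enters the shoot almost unselectively with
the water that travels the apoplastic ("bypass") path into the root
xylem. The share of water taking that path declines linearly with air
relative humidity (`RJvB = -0.0275·RH + 3.92`, %), so the bypass flux is
`JvB = Tr_act · RJvB / 100` (mm d⁻¹). Suberin lamellae in the root exo-
and endodermis progressively block the path: the relative remaining
bypass flow is

`RRBF = (rrbf_min / 100) ^ ((SC - SC_min) / (sc_max - SC_min))`,

equal to 1 for an unsuberized root and `rrbf_min`% for a maximally
suberized one. Root suberin content `SC` is a saturating function of
development stage (DVS, 0 = emergence, 1 = anthesis, 2 = maturity) and of
a salinity-driven deposition response
`F_sc = (Na_ext / max_na_ext) / (1 - sub_dep_eff)` (clamped to [0, 1]).
Apoplastic uptake converts water flux times molarity into mass per
hectare (1 mm over 1 ha = 10⁴ L; 1 mM Na⁺ = 22.99 mg L⁻¹), and is scaled
to the *total* shoot uptake by the bypass share of total Na⁺ uptake,
itself a linear function of humidity calibrated so the 58–92% RH band
maps onto the 35–22% bypass share reported for rice.

**2. Allocation.** The culm sequesters Na⁺ at a genotype-specific
potential rate damped by a feedback on how full the culm sink already is;
the feedback term goes negative for a nearly full sink and is floored at
zero, and the rate is additionally capped by the day's uptake and by the
concentration ceiling `na_culm_max`. During 0.6 ≤ DVS ≤ 2 a fraction
`par_p · na_to_pan` of the surplus follows the photosynthate stream into
the panicle. The exact residual reaches the leaves and is split across
canopy layers with geometric weights `(1 - part_cap)^((i-1)/(N-1))`
(layer 1 = bottom = oldest), so older leaves shield younger ones. Mass is
conserved to machine precision every day; the test suite checks closure
to 10⁻⁹ relative over full seasons.

**3. Stress factors.** Tissue concentrations feed back on the host
through five multipliers:

* *Photosynthesis* (`RPn`, per layer): a beta-type response of the layer's
  leaf Na⁺ concentration — 1 up to `thresh_l`, 0 at `crit_l`, strictly
  decreasing between, with the supra-threshold factor raised to
  `(crit_l - thresh_l)/(thresh_l - na_leaf_min)`. `RPn` also accelerates
  the layer's senescence (death rate × `(1 + k_sen·(1 - RPn))`).
* *Maintenance respiration* (`MRespF`): linear ramp of the mean leaf
  concentration from 0.5 to 3 mg g⁻¹; leaf and culm maintenance are
  multiplied by `1 + MRespF`, so respiration doubles at 3 mg g⁻¹.
* *Spikelet sterility*: `susc_st · [Na⁺]_panicle · bellF` inside
  0.6 ≤ DVS ≤ 1.1, where `bellF` peaks at booting (DVS 0.8) and flowering
  (DVS 1.0); the daily photosynthate flux to panicles is multiplied by
  `1 - SterilityF`.
* *Osmotic effects*: quadratics in the external molarity reduce specific
  leaf area (`SLAstress`) and culm expansion (`CVSstress`).

**4. Host growth.** A deliberately minimal SUCROS/WOFOST-style engine
supplies the coupling points: thermal-time phenology, Beer-law
interception, radiation-use-efficiency growth weighted by the
light-weighted mean of the per-layer `RPn`, Q10 maintenance respiration,
tabulated dry-matter partitioning, SLA-driven leaf-area expansion,
senescence, and transpiration proportional to intercepted reference
evapotranspiration. The canopy is re-cut every day into `n_layers`
equal-biomass layers ordered by age (a conservative re-binning along the
cumulative-biomass axis transports layer Na⁺ exactly), so "the oldest
tissue" always sits in the bottom layer.

## Design choices where the formulation was open

Several constants and functional arrangements are not fixed by the
published formulation; the package resolves each one explicitly, exposes
it in the configuration, and records the resolved value in every
provenance file.

* **Bypass-flow arrangement.** The printed form of the suberin response
  places the factor 1/100 outside the power, which makes bypass flow
  *increase* with suberin content (0.01 at `SC_min` to 0.05 at `sc_max`)
  — the opposite of the stated physiology. The canonical mode implements
  the monotone-decreasing form `(rrbf_min/100)^fraction`; the printed
  arrangement is available as `rrbf_literal` for audit runs.
* **Photosynthesis response.** The printed expression raises the whole
  two-factor product to `((crit_l - thresh_l)/(thresh_l - na_min))^C`,
  which exceeds 1 and explodes between the threshold and the critical
  concentration. The exponent's value is exactly the supra-optimal
  exponent of the standard beta response used throughout crop modelling,
  so the canonical mode applies it to the supra-threshold factor only,
  which satisfies the stated boundary behaviour (1 at `thresh_l`, 0 at
  `crit_l`, strictly decreasing between, stationary maximum at the
  threshold). The verbatim arrangement is kept as `rpn_literal`.
* **`max_na_ext` (300 mM).** The external concentration at which suberin
  deposition saturates is unprinted. Setting it near sea-water salinity
  keeps the deposition response sub-saturated and monotone over the whole
  0–50 mM experimental range (with the default deposition efficiency the
  response saturates at ≈114 mM). A value at the strongest chamber
  treatment (50 mM) would make any field salinity above ≈19 mM suberize
  roots fully at emergence, which contradicts both the age-limited
  development of root barriers and the monotone increase of plant Na⁺
  content across treatments.
* **`SC_min` = 0 mg g⁻¹, `na_leaf_min` = 0 mg g⁻¹, `C` = 1.** Neutral
  defaults for unprinted constants; all configurable.
* **Bypass share of total uptake.** Only the 22–35% range is reported;
  the default linear relation maps RH 58% → 35% and RH 92% → 22%, and the
  coefficients are configuration fields, not ground truth.
* **`SLAstress` clamp.** The raw quadratic exceeds 1 for 0–40 mM, implying
  that mild salinity *increases* leaf expansion. Because the factor is
  defined as a 0–1 reduction factor, the default clamps at 1; the raw
  quadratic is available via `sla_clamp = FALSE`.
* **Sterility bell.** Implemented as the maximum of two Gaussian bells
  (σ = 0.05 DVS) centred on booting and flowering, zeroed outside
  [0.6, 1.1]; centres, width and window are configurable.
* **Senescent Na⁺.** Na⁺ in tissue that dies moves to a dead-tissue
  ledger and leaves the active-leaf concentrations, consistent with the
  purpose of trait T4 (old leaves as a disposable Na⁺ sink). The ledger
  participates in the mass balance; `retain_senescent_na = TRUE` keeps
  the Na⁺ in the living layer instead.
* **Panicle concentration ceiling.** None is imposed: the formulation
  gives no cap for panicle Na⁺, and the sterility factor is already
  clamped to [0, 1].

## The host engine and why it is shaped this way

The host is not a re-implementation of any full crop model; it exists to
provide the coupling surface (transpiration, DVS, partitioning shares,
per-layer leaf biomass) with as little machinery as possible. Two design
points deserve mention.

*Stem reserves.* With purely tabulated partitioning, an osmotically
stunted culm would *save* more maintenance respiration than it cost in
yield, so salinity could perversely raise grain yield. Real rice fills a
substantial share of its grain from stem reserves accumulated before
anthesis. The engine therefore remobilizes up to 30% of the culm biomass
present at anthesis to the panicle (4% of the remaining allowance per
day), restoring the culm's yield function; the Na⁺ bound to the
remobilized fraction is fixed in structural tissue. With this in place,
every stress channel reduces yield, and hydroponic treatments at
0/10/25/35/50 mM produce monotonically non-increasing yields.

*Scale.* Default host parameters (RUE 3.0 g MJ⁻¹ intercepted PAR,
thermal-time requirements 1100 + 600 °Cd above 8 °C, plant density
2.5 × 10⁶ plants ha⁻¹, five canopy layers, transplanted-seedling initial
biomass) give unstressed yields around 8–9 t ha⁻¹ over a 130-day
temperate season — the scale of high-input temperate rice systems — and
salinity losses of roughly 10–20% under the two field scenarios.

## Synthetic forcing

`make_weather()` generates a temperate rice season: half-sine seasonal
curves for temperature (16–25 °C) and radiation (14–24 MJ m⁻² d⁻¹) with
bounded AR(1) noise, relative humidity confined to 58–92%, and reference
evapotranspiration derived from radiation and temperature. A seed fully
determines a season; distinct seeds stand in for distinct years of a
weather archive. The generator makes no claim to reproduce any particular
station record: it lacks weather fronts, typhoons, monsoon structure and
radiation–humidity covariance, so conclusions drawn from it concern the
model's behaviour, not any real district.

`make_salinity_series()` provides two archetypal field-water salinity
dynamics: an *early peak* (linear rise to 3.5 dS m⁻¹ within the first
third of the season, then exponential decay over about two weeks when
fresh water returns, e.g. after water-holding for herbicide application)
and a *gradual ramp* (rise to 2.5 dS m⁻¹ by mid-season, constant to
harvest, as in districts where saline soils feed the irrigation water).
Conversion uses the dilute-NaCl approximation 10 mM per dS m⁻¹,
configurable. The shapes are idealized piecewise curves; the day of the
fresh-water inflow has no canonical value and is a scenario parameter.

The hydroponic mode emulates a growth-chamber protocol: constant
day/night temperatures 26/18 °C (14 h photoperiod, thermal-time mean
22.7 °C), constant lamp radiation, humidity cycling inside 58–92%, and a
constant NaCl treatment concentration.

## Sensitivity analysis and ideotyping

The ideotyping workflow asks which traits explain the variance of final
yield under a given salinity scenario. Marginals are normal, centred on
the trait means with standard deviations of 5% of the mean, truncated at
±4 sd and at physical bounds, and treated as independent (no correlation
structure is published). The design size follows the rule
`M = 2^(q+3)·(2n+2)`, smallest such `M` strictly exceeding `γ·n`; with
the ten trait parameters and γ = 500 runs per parameter this gives 5632
model runs (base sample N = 256). `saltelli_sample()` draws A and B from
a seeded Latin hypercube and stacks A, B, AB_i and BA_i blocks;
`sobol_indices()` uses the symmetric Jansen estimators (chosen for their
variance efficiency; the estimator is not prescribed by the formulation)
with bootstrap confidence intervals over resampled base rows. The
estimators are verified in the test suite against the closed-form indices
of an additive linear model and of the Ishigami function at N = 1024.
The ideotype is simply the sampled parameter vector with the highest
yield, ties broken by the lowest row index.

Because a full Saltelli design at N = 256 costs 5632 season runs per
scenario, the routine property checks in the test suite run the workflow
at N = 32 (704 runs) over several seeds and only assert the *ordinal*
outcome — which trait group tops the total-order ranking under each
scenario archetype; N = 256 remains the default for real analyses via
`cmd_sensitivity()`.

## Numerical and degenerate-input conventions

* All clamps are two-sided and explicit (`F_sc`, `RPn`, `MRespF`,
  `SterilityF`, sink size, osmotic factors); the Eq.-8 feedback and the
  uptake-minus-sequestration surplus are floored at zero.
* `suberin_content()` resolves its indeterminate corner
  (DVS = 0, `F_sc` = 1) to 0, the limit along the age axis.
* `leaf_layer_partition()` treats one layer and `part_cap` = 1 as exact
  limits (everything to the single/bottom layer).
* Layer re-binning is exactly conservative by construction; season-long
  Na⁺ closure errors are at the 10⁻¹⁵ level.
* Zero salinity short-circuits the salt module; such runs are verified to
  be bit-identical to a host-only simulation.
* Weather and design generation save and restore the global RNG state,
  so library calls do not perturb user-level reproducibility.

## Known limitations

* K⁺ dynamics and the Na⁺:K⁺ ratio are not represented; toxicity is
  driven by Na⁺ concentration alone.
* Osmotic adjustment and stomatal responses are only implicit in the two
  quadratic osmotic factors.
* The host engine does not simulate tillering, individual leaf size,
  nitrogen, or a soil water/salt balance; field-water salinity is an
  exogenous forcing.
* Transmembrane (HKT-mediated) uptake is not modelled mechanistically;
  genotypic differences act through the bypass pathway only, and the
  transmembrane share enters only through the fixed humidity-dependent
  scaling.
* Reported evaluation statistics for the original growth-chamber
  experiments are not reproducible here: the underlying measurements,
  reanalysis weather and the external host parameterization are not
  published. The package's own tests therefore rely on conservation
  laws, closed-form benchmarks and ordinal patterns rather than on those
  headline numbers.
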