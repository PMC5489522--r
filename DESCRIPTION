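Package: saltrice
Title: Trait-Based Simulation of Salt Stress in Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily, trait-based simulator of sodium toxicity in rice
    (Oryza sativa). Shoot Na+ uptake through the apoplastic (bypass-flow)
    pathway is modulated by dynamic suberin deposition; sodium is allocated
    among culm storage, panicles and leaf layers by age; tissue
    concentrations feed back on photosynthesis, senescence, maintenance
    respiration, spikelet sterility and organ expansion. The salinity
    module is coupled to a minimal multilayer radiation-use-efficiency
    crop engine, with a hydroponic forcing mode for growth-chamber style
    experiments. Includes synthetic weather and field-water salinity
    scenario generators, Sobol' variance-based sensitivity analysis with
    Saltelli sampling for trait ideotyping, and standard model-evaluation
    statistics (RRMSE, modelling efficiency, coefficient of residual mass,
    R squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
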