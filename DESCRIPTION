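Package: plumetox
Title: Passive Sampling, Plume Dispersal and Toxicity Thresholds for
    Aquaculture Delousing Discharge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the environmental risk of pyrethroid bath
    treatments (deltamethrin) discharged from salmon farms. Calibrates
    silicone-rubber passive samplers via the cosolvent method and
    performance-reference-compound (PRC) exchange kinetics, converts
    absorbed amounts to water concentrations under alternative
    exposure-duration scenarios, simulates depth-integrated passive-tracer
    dispersal of sequential cage releases on a regular grid, reduces
    concentration histories to impact metrics (area, extent and duration
    above a lethal threshold, dilution factors, sediment risk margins),
    and derives the lethal-effect threshold from tank-level shrimp
    exposure experiments. A synthetic-data module generates every input
    with known ground truth so the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
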