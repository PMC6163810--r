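Package: protonGating
Title: Proton-Transport Analysis of Voltage-Sensor-Domain Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the proton-transport interpretation of
    gating current in voltage-gated ion channels. Provides slab and
    center-of-charge analysis of atomic partial charges along the membrane
    normal, book-keeping of protonation-state energies across applied
    voltages with crossing-point location, Q10/activation-energy and
    thermal-mode arithmetic, Boltzmann and Gaussian-threshold models of
    open-probability curves, conductance-free-energy barrier diagnostics,
    and hydrogen-bond site-graph analysis (Y/R/E and R-E-R triad detection,
    proton-path enumeration with the amphoteric-arginine rule). A synthetic
    data module generates charged structures, state-energy tables and
    gating datasets with planted ground truth so every stage is testable
    without quantum-chemistry outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
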