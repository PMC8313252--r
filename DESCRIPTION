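Package: phytscreen
Title: Simulation and Analysis of HPLC Screens for Phytase Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening phytase (myo-inositol hexakisphosphate
    phosphohydrolase) activity from HPLC inositol-polyphosphate profiles.
    Provides the stereochemical algebra of the 64 myo-inositol phosphorylation
    states and their chromatographic equivalence classes, linear
    master-equation simulation of enzymatic phytate dephosphorylation by
    position-preference enzyme and community models, synthesis and analysis of
    detector traces (peak detection, integration, retention-time assignment,
    quantification), and rule-based inference of the phytase class (3-phytase,
    4/6-phytase, 5-phytase, MINPP-like, mixed community) from InsP5 isomer
    patterns, together with calibrated synthetic scenarios emulating pure
    isolates and soil communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
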