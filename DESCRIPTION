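Package: piliwire
Title: Charge-Transport Analysis for Conductive Protein Nanowires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of single-fiber electrical measurements on
    conductive bacterial pili (protein nanowires): ohmic resistance fits of
    conductive-probe AFM current-voltage sweeps, resistance-versus-distance
    regression with linear/exponential model selection, conductivity and
    resistivity under explicit fiber-diameter conventions, electron-transport
    rates, detection and fitting of the ohmic to space-charge-limited
    transport crossover with carrier mobility and concentration estimates,
    aromatic side-chain contact statistics and density maps from multi-model
    PDB fiber trajectories, scanning-tunneling spectroscopy processing
    (sweep averaging, differential conductance, band-gap detection,
    topographic periodicities, tip-deconvolution), and optical/elemental
    screening for redox cofactors. Includes seeded synthetic-data
    generators for every input so each analysis stage is testable against
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
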