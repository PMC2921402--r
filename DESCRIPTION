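Package: dielcycle
Title: Diel Cell-Cycle Analysis of DNA-Content Flow Cytometry for
    Light/Dark-Synchronized Picocyanobacteria
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the diel cell cycle of
    light/dark-entrained picophytoplankton populations from DNA-content
    flow cytometry. Provides a synthetic-population simulator for
    L/D-synchronized cultures under modulated visible and ultraviolet
    irradiance, constrained Gaussian-mixture deconvolution of DNA
    histograms into G1/S/G2 fractions (a Dean-Jett-Fox-style model with
    the G2 peak constrained to twice the G1 position), peak-timing and
    phase-duration estimation from diel phase-fraction curves (the
    twice-the-peak-delay rule), cell-cycle-based (Carpenter-Chang) and
    cell-count-based growth-rate estimators, a between-condition phase
    delay estimator based on circular cross-correlation, and
    comparative-CT (delta-delta-CT) relative quantification for diel
    qPCR designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
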