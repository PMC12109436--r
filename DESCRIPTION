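Package: fontanjet
Title: Entrainment Characterization for Injection-Jet-Assisted Fontan
    Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reduced-order (0D) lumped-parameter simulation of Fontan
    total cavopulmonary circulation with four two-element Windkessel
    compartments, a pulsatile pump source and resistance tuning to
    prescribed systemic and pulmonary flow splits; generation of the
    20-case continuous and five-burst pulsed catheter injection protocol;
    synthetic mock-flow-loop sensor records with programmable jet
    entrainment and seeded noise; zero-phase Butterworth and
    Savitzky-Golay waveform denoising; stage and burst segmentation of
    injection transients; step-response jet characterization (rise, fall,
    settling, overshoot, relaxation time); and flow-entrainment
    quantification with sweep-level summary matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
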