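Package: flyemd
Title: Hybrid Elementary-Motion-Detector Model of Fly Direction Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a three-arm elementary motion
    detector of the kind implemented by Drosophila T4 cells, combining
    multiplicative preferred-direction enhancement with divisive null-direction
    suppression. Generates visual stimuli (single-column light pulses, apparent
    motion sequences, drifting gratings) as space-time luminance movies, models
    the lamina L1 front-end (first-order temporal filtering, DC restoration,
    rectification), runs single detector units, detector arrays and the opponent
    tangential-cell stage, and quantifies responses the way calcium-imaging
    studies do (dF/F, baseline-subtracted peak or mean amplitudes, linear
    expectation and nonlinear response components of apparent-motion stimuli,
    receptive-field maps on the hexagonal ommatidial lattice, temporal-frequency,
    direction and onset-delay tuning curves, a direction-selectivity index).
    Includes a generator of synthetic calcium-like recordings (hexagonal
    receptive fields, slow indicator kernel, trial noise, few repetitions) so
    every analysis stage is testable without recorded data, and a
    configuration-driven experiment runner with flat-file CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
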