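Package: thetamaze
Title: Theta-Band EEG and Water-Maze Analysis for Multi-Site Rodent Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral and coherence analysis of multi-site theta-band EEG
    (supramammillary nucleus, medial septum, dentate gyrus, CA1) recorded
    during Morris water-maze place learning, together with swim-trajectory
    performance metrics and the associated repeated-measures statistical
    battery. Absolute and relative power are computed on a 4-12 Hz, 0.5 Hz
    grid from 2-s epochs; magnitude-squared coherence is estimated for all
    region pairs with peak-frequency tracking and cross-region correlation.
    A synthetic-cohort generator produces multi-channel local field
    potentials with known spectral peaks and coherence targets, plus biased
    random-walk swim paths, so every pipeline stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
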