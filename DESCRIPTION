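Package: screensift
Title: Plate-Based RNAi Rescue-Screen Scoring, Filtering and Decay Kinetics
Version: 0.1.0
Authors@R:
    person("Screen", "Analyst", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for viability rescue screens run in 384-well
    plates with an siRNA library against an inducible lethal stimulus.
    Implements per-plate median normalization, experiment-wide robust
    (median/MAD) Z-scores with triplicate summarization, threshold hit
    calling, counter-screen and expression filtering as a reported cascade,
    siRNA pool deconvolution with synergy-pool classification, and mRNA or
    protein half-life estimation from transcription-shutoff time courses by
    log-linear decay fitting.  A seeded synthetic-data generator emulates the
    statistical structure of such a screen (lethal induction, planted
    rescuers, off-target pools, induction inhibitors, plate scale effects,
    multiplicative well noise) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
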