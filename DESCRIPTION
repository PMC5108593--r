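Package: flyforage
Title: Trajectory-Based Analysis of Drosophila Patch Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse video-tracking trajectories of single
    Drosophila melanogaster foraging in a circular arena with discrete
    yeast and sucrose patches. Smooths head/body trajectories, classifies
    each frame into rest, micromovement or walking with a sharp-turn
    overlay, detects patch encounters, food micromovements and visits via
    distance and hysteresis merge rules, computes per-fly
    exploitation/exploration parameters (stop probability, visit
    durations, transition probabilities to same/adjacent/distant patches,
    yeast quartile dynamics), and compares groups with rank-sum,
    Fisher-exact and bootstrap median-difference procedures. A
    semi-Markov forager simulator with ground-truth event logs makes the
    full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
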