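Package: sasmd
Title: Self-Adaptive Steered Molecular Dynamics on Synthetic Binding Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for self-adaptive steered molecular dynamics
    (SA-SMD): constant-velocity harmonic pulling of a surrogate ligand out of
    synthetic anisotropic binding-funnel energy landscapes, with the pulling
    direction periodically re-optimized by minimizing the windowed average
    stretching force with a multi-population, information-entropy genetic
    algorithm. Includes an overdamped Langevin engine with exact
    checkpoint/restore, the conventional fixed-direction SMD driver, rupture
    force extraction from 1-ps windowed force profiles, and experiment
    orchestration (cut-off-force and pulling-rate sweeps, paired C-SMD/SA-SMD
    comparisons, and rupture-force versus binding-energy correlation over
    synthetic complex families).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
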