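Package: forcespec
Title: Simulation and Analysis of Single-Molecule Force Spectroscopy of
    Metalloprotein Unfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for atomic force microscopy single-molecule force
    spectroscopy (AFM-SMFS) of polyprotein unfolding, centred on
    metallothionein metal-thiolate cluster rupture. Provides worm-like chain
    (WLC) polymer elasticity, contour-length-increment arithmetic and
    Bell-Evans force-activated rupture kinetics; a kinetic Monte-Carlo
    constant-velocity pulling simulator that produces sawtooth
    force-extension curves with per-event ground truth; a curve analysis
    pipeline (baseline correction, peak detection, per-branch WLC fitting,
    contour-length increments, marker-fingerprint selection); classification
    of metallothionein alpha-domain events into one-step and two-step
    unfolding pathways with anchoring-cysteine and N/C direction assignment;
    and dynamic force spectroscopy fitting of the Bell-Evans model to
    recover zero-force off-rates and transition-state distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
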