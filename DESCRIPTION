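Package: kindyn
Title: State Descriptors, Collective Modes and Cryptic-Pocket Detection for
    Kinase-Domain Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of protein
    kinase domains. Computes activation-state descriptors (DFG-motif
    cyclization, alphaC-helix positioning, salt-bridge occupancies), B-factor
    and segment-convergence profiles, quasi-harmonic collective modes of
    concatenated multi-state ensembles with state-discrimination statistics,
    and grid-based transient (cryptic) pocket detection with per-frame volume
    tracking. Ships a seeded synthetic-trajectory generator that plants five
    kinase activation-state profiles (inhibitor-bound, apo and three
    phosphorylation variants) with known descriptor targets, collective
    motions and a gated cavity, so every analysis stage can be validated
    against ground truth without rerunning molecular dynamics. Reads and
    writes PDB and DCD trajectories; results are tidy tibbles with ggplot2
    autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
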