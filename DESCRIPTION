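Package: thermotraj
Title: Trajectory Descriptors for Comparative Protein Thermal-Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analyse protein molecular-dynamics trajectories for thermal-stability
    comparisons: optimal superposition and RMSD, radius of gyration, per-residue
    RMSF, the Best-Hummer-Eaton fraction of native contacts, geometric hydrogen-bond
    and salt-bridge detection with replica-averaged frequencies, stability
    classification and interaction-network motifs (dyads, triads, tetrads), a
    self-contained DSSP-style secondary-structure assignment with a three-class
    collapse, and pooled replica statistics with percent-change comparisons.
    Ships seeded synthetic-trajectory generators (ideal helices, beta hairpins,
    rigid-body, fluctuation, unfolding and intermittent-contact trajectories)
    so every analysis stage has a ground-truth recovery test at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
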