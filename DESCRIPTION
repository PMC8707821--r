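Package: cypallo
Title: Allosteric H1 Site Analysis for Membrane-Anchored Cytochrome P450 Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for molecular-dynamics studies of the
    conserved superficial allosteric site (H1) on drug-metabolizing cytochrome
    P450 enzymes. Provides alignment-based conservation scoring of the
    18-residue H1 site by physicochemical groups, membrane-model validation
    metrics (heme tilt angle, burying depth, radius of gyration, RMSD/RMSF),
    per-residue ligand-association hotspot scores and probe occupancy z-score
    grids, CAVER-style tunnel bottleneck comparison with a grid-based
    widest-path bottleneck finder, metadynamics bias reconstruction from
    deposited Gaussian hills with ligand-egress readouts (dissociation time
    and maximal potential), and Welch t-tests from summary statistics for
    outcome tables. A synthetic-data generator produces membrane systems,
    ligand random walks, alignments, clearance grids and hills schedules with
    known ground truth so every stage is testable without microsecond
    trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
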