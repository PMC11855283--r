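Package: paratopeVox
Title: Surface-Based Paratope Prediction with Voxel Features and a Hybrid
    3D-CNN/Transformer Scoring Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end antibody paratope (binding-site) prediction from
    structure alone. Reads and cleans antibody/antigen PDB structures,
    generates a dot-sampled solvent-accessible surface with outward normals
    (or ingests DMS dot files), performs balanced sampling of binding and
    non-binding surface points, builds normal-aligned 41x41x41 voxel grids
    with 22 per-atom chemical and force-field channels, scores surface
    points with a hybrid 3D residual network plus transformer block,
    aggregates point scores to residues by their maximum, and evaluates
    predictions over IMGT-defined CDR/framework regions (CDR+-2, Fv, Fab)
    with AUC-ROC, AUC-PR, F1, MCC and companion metrics, including a
    per-position frequency baseline. Ships deterministic synthetic-complex
    and planted-signal grid generators so the whole pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
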