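Package: curvagn
Title: Curvature-Based Adaptive Graph Networks for Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-ligand binding affinity from 3D complex structures
    with a curvature-based adaptive graph attention network. Builds directed
    complex interaction graphs from atom coordinates, attaches multiscale
    Ollivier/Forman Ricci curvature profiles computed over distance filtrations,
    and runs angle-domain adaptive attention message passing with an
    interaction-matrix auxiliary objective. Includes a reproducible synthetic
    complex generator so every stage is testable without external structure
    downloads, plus training, evaluation metrics (RMSE, MAE, Pearson R,
    regression SD) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    boot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
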