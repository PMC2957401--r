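Package: surfalign
Title: Local Structural Alignment of Protein Surface Patches by Global
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body alignment of protein binding sites represented as
    labelled atom point clouds. Superpositions are parameterized by a unit
    quaternion plus translation and found by a controlled random search
    (CRS) global optimizer that minimizes either the classical closest-point
    objective or an injective matching distance defined through an
    asymmetric (rectangular) assignment problem on a physico-chemically
    filtered bipartite graph. Includes an iterative closest point (ICP)
    baseline, binding-site extraction from PDB files with donor/acceptor/
    aliphatic/aromatic atom typing, post-alignment scores (aligned atoms,
    RMSD, SAS, normalized similarity), all-vs-all comparison matrices with
    ROC retrieval evaluation, and a synthetic-instance generator with known
    ground-truth transforms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
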