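Package: iawall
Title: Multimodal Exploration of the Intracranial Aneurysm Wall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for combining histology, micro-CT and hemodynamic data of
    a resected intracranial aneurysm dome. Provides stain classification and
    stain-aware tissue segmentation of histologic images, visibility-based
    inner/outer labelling of wall mesh vertices and contour points, virtual
    inflation of the collapsed dome mesh toward the preoperative lumen model,
    section-based transfer of histologic pixel values onto micro-CT slice
    masks, rigid ICP registration with nearest-vertex transfer of per-vertex
    scalar fields (e.g. wall shear stress) onto voxel grids, and seeded
    synthetic phantoms with ground truth for every input so the whole
    pipeline runs without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    nnet,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
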