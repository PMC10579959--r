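Package: atrialign
Title: Automated Rigid Alignment of Left Atrial Surface Anatomies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated rigid alignment of left atrial (LA) surface
    anatomies segmented from pre-procedural CT/MRI with anatomies acquired by
    electro-anatomical mapping (EAM) systems during ablation procedures.
    Implements a two-stage iterative closest point registration with a
    point-to-plane residual: stage one aligns the full anatomies including the
    pulmonary veins, appendage and mitral annulus (the most distinctive
    landmarks), stage two refines the alignment after excluding those
    structures, capped at three iterations. Includes isotropic remeshing of
    non-uniform segmentation exports, residual-distance quality metrics
    (median, percentage of surface below 2.5/5 mm), surface I/O for
    PLY/OBJ/STL and a plain-text point format, and a synthetic labeled LA
    phantom generator with a simulated EAM acquisition providing ground-truth
    transforms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
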