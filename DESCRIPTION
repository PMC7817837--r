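Package: blebkinetics
Title: Quantitative Image Analysis of Cytoplasmic Fluidity and Membrane
    Bleb Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify cytoplasmic fluidity and membrane-bleb
    kinematics from time-lapse fluorescence microscopy. Implements
    single-particle tracking of cytoplasmic probes (Laplacian-of-Gaussian
    spot detection, prominence-based maxima selection, stable-marriage
    frame-to-frame linking), mean-square-displacement analysis with
    diffusion-coefficient estimation, radial contour kinematics of blebbing
    cells (tricolor expansion/retraction maps, bleb morphometrics,
    expansion/retraction phase annotation), fluorescence-ratio and
    kymograph quantification, and a synthetic-movie generator with known
    ground truth for validating every stage end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
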