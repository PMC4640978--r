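Package: boneSPM
Title: Cortical Bone Mapping, Shape Modelling and Surface Statistical
    Parametric Mapping of the Proximal Femur
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the spatial distribution of cortical bone
    over the proximal femur. Implements cortical bone mapping (estimation of
    cortical thickness, cortical bone mineral density and cortical mass
    surface density from CT-style intensity profiles via a blur-aware
    three-level model with global-then-local constrained fitting), canonical
    surface registration (rigid and Laplacian-regularised nonrigid ICP) with
    data transfer and surface smoothing, point-based statistical shape models
    by principal component analysis, vertex-wise general linear models with
    family-wise-corrected statistical parametric mapping (Freedman-Lane
    permutation and approximate random-field theory), and patch-level effect
    quantification. A synthetic femur-cohort generator with planted covariate
    effects makes the whole pipeline testable end to end without any imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
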