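Package: latticeRT
Title: Radiobiological Evaluation of Lattice and Spatially Fractionated
    Radiotherapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based radiobiological comparison of lattice and other
    spatially fractionated radiotherapy prescriptions for bulky
    heterogeneous tumors. Builds a voxelized concentric-spheroid phantom
    with necrotic, hypoxic and normoxic subvolumes plus skin and
    chest-wall organs at risk, synthesizes idealized 3D dose
    distributions for conformal and lattice boost courses, converts dose
    to EQD2 voxel-wise, extracts dose-volume histograms, and evaluates
    Poisson linear-quadratic tumor control probability, generalized
    equivalent uniform dose and Lyman-Kutcher-Burman normal tissue
    complication probability, together with a three-compartment
    linear-quadratic cell-survival course model with oxygen enhancement
    ratio modified radiosensitivity and optional exponential regrowth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
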