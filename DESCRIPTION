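Package: lvemech
Title: Electromechanics of the Left Ventricle with Fibre and Sheet
    Microstructure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulation pipeline for studying how myocyte
    (fibre) and laminar (sheet) microstructure shape the contraction of
    an idealized rat left ventricle. Builds truncated-ellipsoid
    tetrahedral meshes, generates rule-based and regionally fitted
    fibre/sheet fields, solves the monodomain equations with an
    anisotropic conductivity tensor and a phenomenological cell model,
    solves quasi-static orthotropic finite elasticity with active fibre
    stress and follower endocardial pressure, and derives global
    (ejection fraction, wall thickening, base-to-apex shortening) and
    local (cylindrical Lagrangian strain) deformation metrics. Includes
    a synthetic-data module that emulates diffusion-tensor-MRI fibre
    observations and analytic motion fields with closed-form strains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    xml2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
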