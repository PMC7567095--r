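Package: tmsfield
Title: TMS-Induced Electric Field Modelling in Small-Animal Head Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the electric field induced by transcranial
    magnetic stimulation (TMS) in small-animal heads. Builds individual
    volume conductor models from computed-tomography volumes (threshold
    segmentation, morphological closure, iso-surface extraction and
    isotropic remeshing), models figure-of-eight coils as magnetic-dipole
    quadratures, and computes the induced electric field with either a
    closed-form spherically symmetric conductor model or a linear-collocation
    boundary element method driven through reciprocity with the
    magnetoencephalography forward problem. Supports a single closed
    skull-with-holes surface floating inside the body compartment, a
    synthetic rat-like phantom generator for validation, field comparison
    metrics (relative error, correlation error, angular error, peak
    displacement), and config-driven placement-grid comparison runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
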