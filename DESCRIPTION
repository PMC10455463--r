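Package: cranioforge
Title: Patient-Specific Porous Cranial Implant Design and Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for designing and quantitatively assessing
    patient-specific porous polyether-ether-ketone (PEEK) cranial implants.
    Covers the complete workflow: CT-like volume segmentation to a watertight
    skull surface, mirror reconstruction of a unilateral segmental defect
    across the fitted midsagittal plane, implant design as an offset shell
    with a solid fixation rim and a diamond-lattice porous core solved to a
    target porosity, a linear static tetrahedral finite-element strength
    check (von Mises stress, deformation), and fitting-accuracy analysis
    (iterative-closest-point alignment, signed surface deviation, accuracy
    decomposition, gap analysis, and a one-sample t-test on expert aesthetic
    scores). A synthetic skull-phantom generator with controlled ground truth
    replaces patient imaging so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
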