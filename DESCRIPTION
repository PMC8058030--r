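Package: sctqa
Title: Geometric and Dosimetric Quality Assurance for Synthetic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance metrics for synthetic CT (sCT) volumes used in
    MRI-only radiotherapy planning of the head and neck. Implements tissue-class
    HU error metrics (ME, MAE), overlap metrics (Dice, Hausdorff), radial
    water-equivalent depth profiles, DVH-parameter dose comparison with skin and
    organ-at-risk gating rules, local-normalisation 3D gamma analysis, and paired
    TOST equivalence testing, together with a seeded head-and-neck digital
    phantom and a toy attenuation dose engine so the full pipeline can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
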