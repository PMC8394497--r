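Package: t2asym
Title: Contralateral Signal and Texture Features from Dual-Echo T2 Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, testable pipeline for studying progression from
    mild cognitive impairment to Alzheimer's disease with quantitative T2
    relaxometry. Estimates voxel-wise T2 maps from a dual fast spin-echo
    pair via the closed-form two-point solution, rigidly registers an
    anatomical-space multi-region segmentation onto the map, extracts a
    38-feature regional radiomics vector (volume, intensity-histogram
    statistics, and intensity-weighted mass-scatter texture), folds features
    of mirrored left/right regions into contralateral means and absolute
    differences, screens features with Wilcoxon rank-sum tests under
    Benjamini-Hochberg false-discovery control, and benchmarks feature
    filters crossed with classifiers under repeated stratified holdout.
    Includes a synthetic dual-echo phantom cohort generator with known
    ground truth so that every stage can be validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    FNN,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
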