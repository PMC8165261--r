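Package: qbcselect
Title: Query-by-Committee Active Learning for MRI Slice Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transfer-learning-friendly active learning toolkit for binary
    grading of brain-tumor MRI slices (high-grade vs. low-grade glioma).
    Implements committee uncertainty scoring (predictive entropy plus
    pairwise Kullback-Leibler disagreement), ranked-range sample selection
    with extreme exclusion, annotation-cost accounting, construction of
    labeled 2D slice datasets from volumetric multi-modality scans with
    voxel-wise segmentation maps, synthetic phantom cohorts and planted
    structure slice tasks for end-to-end testing, and evaluation harnesses
    (ROC-AUC over repeated seeded runs, uncertainty-range sweeps, and
    sample-size sweeps against a random-sampling baseline). The scoring and
    selection machinery is classifier-agnostic: any model exposing fit()
    and predict_proba() can serve as a committee member; a seeded
    SGD-trained multinomial logistic reference classifier is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    RNifti,
    jsonlite,
    yaml,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
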