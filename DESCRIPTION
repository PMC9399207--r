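Package: amypet
Title: Neuropathology-Anchored Amyloid-PET Classification on Synthetic Phantom Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for amyloid-PET image classification validated against
    neuropathological ground truths. Implements balanced-resampling linear
    support-vector-machine ensembles with leave-one-out evaluation under
    class imbalance, mean-classifier construction with top-weight voxel
    selection, signed distance-to-hyperplane scoring, SUVR and Centiloid
    quantification, PET amyloid staging schemes, and the accompanying
    inferential toolkit (ROC with Youden cut-points, dependent
    overlapping-correlation comparison, Welch and rank-based group tests).
    A synthetic phantom module generates end-of-life-like and
    asymptomatic-like cohorts with phase-dependent regional amyloid signal
    so the whole pipeline can be exercised end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pROC,
    quadprog,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
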