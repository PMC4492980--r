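Package: ctnorm
Title: CT-Guided Spatial Normalization and Striatal SUVR Quantification for
    Dopamine Transporter PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial normalization of dopamine-transporter brain PET images
    guided by the accompanying CT from a PET/CT scanner, when no MR image is
    available.  Implements the two CT preparation routes -- piecewise intensity
    transformation (itCT) and probabilistic-atlas skull-stripping (ssCT) --
    together with MR- and ligand-specific PET-template-guided routes on one
    shared registration engine (rigid, affine, and low-frequency cosine-basis
    nonlinear warps).  Provides cohort-level template construction
    (intensity templates, probabilistic tissue maps, thresholded striatal VOI
    templates with subregional parcellation), target-to-cerebellar SUVR
    quantification with percent-bias assessment against ground truth, and the
    evaluation battery (group t-tests, ROC analysis, severity regression,
    mean/SD images, worse-side flipping, permutation-corrected voxelwise
    maps).  A seeded synthetic head-phantom generator supplies cohorts with
    known anatomy, transforms, and uptake for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
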