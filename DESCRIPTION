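Package: brainbias
Title: Bias Correction, Accuracy and Reliability of Clinical Brain-Age Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-prediction statistical machinery for brain-age studies on
    clinical-grade MRI: simulation of multi-modality brain-age predictions with
    a regression-dilution bias, participant-level stratified splitting with
    distribution-equality checks, fitting and cross-validated selection of
    linear bias models, an age-independent inverse bias correction (with the
    naive age-dependent correction for diagnostics), repeated-measures
    bootstrap accuracy metrics (MAE, Pearson correlation, constrained R
    squared), brain-PAD slope-removal tests, mixed-effects within-subject
    comparisons of absolute brain-PAD, and internal-consistency statistics
    (Cronbach's alpha with an F-based confidence interval, within-subject mean
    absolute deviation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
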