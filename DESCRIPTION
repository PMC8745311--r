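Package: fundusdr
Title: Automated Diabetic Retinopathy Screening from Fundus Photographs and
    Diagnostic-Test Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a classical (non-deep-learning)
    automated diabetic retinopathy screening pipeline: fundus image quality
    gating, green-channel vessel extraction, optic disc and macula
    localization, dark (microaneurysm/hemorrhage) and bright
    (exudate/cotton-wool spot) lesion detection in a fovea-centred polar
    coordinate frame, ICDR severity staging with macular-edema and
    sight-threatening flags, and patient-level diagnosis aggregation.
    Includes a synthetic fundus image and screening-cohort generator with
    ground truth and simulated graders, and the full diagnostic-validation
    battery used to benchmark screening graders: sensitivity, specificity,
    predictive values and likelihood ratios with confidence intervals,
    Cohen's kappa with a homogeneity test, single-operating-point ROC AUC
    comparison, Fagan post-test probabilities, and two-proportion tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
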