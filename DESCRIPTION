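Package: radstab
Title: Radiomic Feature Stability and Classifier Generalizability Across CT Acquisition Settings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how CT acquisition and reconstruction settings
    (slice thickness, reconstruction matrix, convolution kernel, image
    transmission route) perturb radiomic features of pulmonary nodules, and
    how that instability propagates into malignancy classifiers. Provides a
    synthetic phantom-nodule cohort generator with simulated reconstruction
    variants, a reduced IBSI-style radiomic feature extractor (first-order,
    shape, grey-level co-occurrence, wavelet / Laplacian-of-Gaussian /
    algebraic filter banks), intraclass-correlation (ICC(A,1)) stability
    stratification, minimum-redundancy-maximum-relevance feature selection,
    Firth-penalized logistic regression, DeLong and McNemar paired tests,
    and a fivefold cross-validation harness that measures model performance
    across simulated test settings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    RNifti
Config/testthat/edition: 3
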