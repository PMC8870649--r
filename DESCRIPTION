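Package: petrad
Title: PET Radiomics Response Analysis for Peptide Receptor Radionuclide Therapy
Version: 0.1.0
Authors@R: person("petrad", "developers", role = c("aut", "cre"), email = "petrad@example.org")
Description: Per-lesion radiomics analysis of somatostatin-receptor PET
    (SUV) images for predicting response to peptide receptor radionuclide
    therapy (PRRT). Implements fixed-bound intensity discretization,
    first-order histogram features (skewness, kurtosis, entropy, energy),
    conventional SUV statistics (SUVmax, SUVmean, MTV, TLG), shape and
    grey-level co-occurrence matrix (GLCM) texture features, per-lesion
    response labeling from paired baseline/follow-up measurements,
    delta-radiomics, point-biserial ranking with forward logistic feature
    selection, linear discriminant classification with stratified k-fold
    cross-validation, ROC/Youden evaluation, per-site (liver, lymph node,
    bone) sub-analyses, and a calibrated synthetic-data generator for the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
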