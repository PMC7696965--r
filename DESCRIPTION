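Package: oralfusion
Title: Dual-Modality Raman and Autofluorescence Classification of Oral Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Quantitative discrimination of oral tumor and adjacent-normal
    tissue from two independent optical modalities: Raman spectra of
    cryopreserved biopsies and VELscope-style autofluorescence images.
    Provides a seeded synthetic cohort generator, Raman preprocessing
    (Savitzky-Golay smoothing, iterative polynomial baseline correction,
    fingerprint-region resampling, normalization, replicate averaging),
    circular-ROI intensity and heterogeneity quantification, from-scratch
    PCA and linear/quadratic discriminant classifiers, principal-component
    level fusion of the two modalities, and confusion-matrix metrics with
    leave-one-out and stratified k-fold cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    MASS,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
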