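Package: ProbeFusion
Title: Multimodal Colon Tumor Discrimination from Fiber-Probe Raman
    Spectra and OCT Enface Textures
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ex vivo colon tumor discrimination combining
    endoscopic-probe Raman spectroscopy and optical coherence tomography
    (OCT). Implements Raman spectral preprocessing (cosmic-spike repair,
    wavenumber and intensity-response calibration, SVD denoising,
    asymmetric-least-squares baseline removal, extended multiplicative
    signal correction, area normalization, Welch band selection), texture
    descriptors for OCT enface images (Gabor filter bank, local binary
    patterns, local phase quantization, gray-level co-occurrence
    matrices), leave-one-subject-out validation of linear discriminant
    classifiers with nested hyperparameter tuning, and sequential
    Bayesian fusion of per-record diagnostic decisions into per-sample
    tumor posteriors with ROC operating-point reporting. A hierarchical
    synthetic cohort generator emulates the clinical data structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
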