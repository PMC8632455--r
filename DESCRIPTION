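Package: ramanff
Title: Raman Spectral Fingerprinting of Follicular Fluid
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A chemometric pipeline for label-discriminative analysis of
    follicular-fluid Raman spectra. Provides spectrum and dataset containers
    with plain-text I/O, a calibrated synthetic-spectrum generator
    (pseudo-Voigt bands on a fluorescence baseline with class-specific zone
    gains), preprocessing (background subtraction, fingerprint cropping,
    vector normalization, wavelet denoising, mean-centering), PCA-guided
    discriminative-zone scanning with Welch tests and band-integration
    quantification, and a small fully connected neural-network classifier
    with holdout, five-fold and leave-one-out evaluation protocols
    (confusion matrices, precision/sensitivity/F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
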