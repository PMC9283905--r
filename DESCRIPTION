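Package: egml
Title: Information-Theoretic Metric Learning for EEG Movement-Intention Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised linear metric learning for multichannel EEG
    classification built on matrix-based Renyi alpha-order entropy
    estimators. Provides conditional-entropy metric learning (CEML),
    entropy-gap metric learning (EGML, a scale-self-limiting
    mutual-information surrogate), and neighborhood component analysis
    (NCA), together with epoch extraction around movement onsets,
    Cartesian Fourier and time-domain feature vectorization, PCA
    conditioning with total-variance normalization, nu-SVM nested
    cross-validation, SVD-sorted per-channel importance maps with
    topographic export, a synthetic 21-channel EEG generator with
    planted readiness-potential-like class structure, and MAT-dialect
    session file I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
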