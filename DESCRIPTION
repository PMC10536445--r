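Package: spo2former
Title: Transformer-Based Per-Second Sleep Apnea Detection from Pulse Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects obstructive sleep apnea events from raw overnight SpO2
    (pulse oximetry) time series at one-second granularity using a
    transformer encoder with interchangeable positional encodings:
    none, constant normalized-index, sinusoidal, and a learnable encoding
    based on a one-dimensional convolutional autoencoder. Includes the full
    preprocessing and windowing pipeline (NaN dropping, per-segment min-max
    normalization, holdout and k-fold splits), a training protocol with Adam
    and plateau learning-rate decay, per-second evaluation metrics
    (accuracy, sensitivity, precision, specificity, F1, ROC AUC), and
    per-patient screening via apnea-hypopnea index (AHI) estimation from
    reconstructed event runs. A bundled synthetic oximetry simulator with
    annotated desaturation events makes the whole pipeline testable without
    clinical data. The neural network forward and backward passes are
    implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
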