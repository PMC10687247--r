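Package: tracheosound
Title: Breathing-Sound Analysis for Tracheostomy Airway Monitoring
Version: 0.1.0
Authors@R: person("Tracheosound", "Developers", email = "tracheosound@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for breathing sounds recorded at the opening of a
    tracheostomy tube. Generates labelled synthetic breath-sound corpora with the
    acoustic structure of normal (NS), vibrant (VS) and sharp (SS) breath sounds,
    high-pass filters low-frequency noise, segments recordings into respiratory
    cycles, extracts short-time Fourier transform spectrograms and mel-frequency
    cepstral coefficients, classifies cycles with a deterministic spectrogram-
    signature rule set and with machine-learning models (kernel SVM, kNN, a small
    convolutional network), and evaluates classifiers with binary and three-class
    metrics including ROC/AUC and accuracy restricted to abnormal sounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
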