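Package: midecoder
Title: Continuous Decoding of Motor-Imagery EEG with Spectrogram-Image
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class (left vs. right hand) motor-imagery
    EEG decoding from three bipolar channels (C3, Cz, C4) sampled at
    250 Hz. Trials are converted to sliding-window short-time Fourier
    transform images (theta-alpha band stacked over an interpolated
    beta band, 40x32x3), classified by small convolutional networks
    built from repeatable "Mega Blocks", trained with SGD-with-momentum
    or Adam, and tuned by Gaussian-process Bayesian optimization with
    expected-improvement or probability-of-improvement acquisitions.
    Continuous-decoding performance is summarised by gross,
    single-trial (majority over 11 windows) and optimal-time-point
    accuracies with Cohen's kappa, for both within-subject and
    leave-one-subject-out transfer protocols. A synthetic
    event-related-desynchronization EEG generator supports end-to-end
    testing without any recording.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
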