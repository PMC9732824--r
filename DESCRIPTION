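Package: neuroaccum
Title: Evidence-Accumulation Modeling of Social and Nonsocial Decisions with
    EEG-Informed fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based analysis of two-alternative economic
    decisions made under social and nonsocial uncertainty. Implements an
    Ornstein-Uhlenbeck evidence-accumulation model with a Kolmogorov-Smirnov
    pseudo-likelihood, two-step fitting and BIC model comparison; behavioral
    statistics (Weibull psychometric likelihood-ratio test, single-trial
    logistic and reaction-time regressions, slope autoregression, power
    analysis); single-trial EEG decoding by sliding-window regularized Fisher
    discriminant analysis with leave-one-out Az, bootstrap significance,
    forward models and per-trial build-up slopes; an EEG artifact pipeline
    (gradient template subtraction, median despiking, bandpass, blink and
    ballistocardiogram component removal); and an EEG-informed fMRI general
    linear model with resampling-based cluster thresholding and
    psychophysiological interaction designs. A synthetic-data module generates
    every input with planted ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
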