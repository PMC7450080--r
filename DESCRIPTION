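Package: eegmedstate
Title: Medication-State Classification from Clinical EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying anticonvulsant medication
    state (phenytoin vs. levetiracetam vs. no medications, within normal- or
    abnormal-EEG strata) from five-minute, 19-channel clinical EEG. Provides a
    synthetic cohort generator with plantable band-power effects and
    clinical-style report text, keyword report labeling with polypharmacy
    exclusion, canonical preprocessing (channel selection, cropping, polyphase
    down-sampling to 100 Hz, zero-phase filtering, common average reference),
    a 570-dimensional quantitative-EEG feature battery (band powers, spectral
    entropies, Lempel-Ziv complexity, Hjorth parameters and other time-domain
    descriptors), max-normalization with PCA or K-best reduction, tuned linear
    and RBF support vector machines, a fixed-configuration random forest, four
    small raw-EEG neural networks with exact trainable-weight accounting, and a
    balanced repeated-split evaluation protocol with a random-label
    Kruskal-Wallis significance test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
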