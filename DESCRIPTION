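Package: painforest
Title: Multimodal Discrimination of Noxious and Non-Noxious Stimulation in
    Infants with Subject-Bootstrapped Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired noxious/control multimodal neonatal recordings
    (EEG at Cz, bilateral limb EMG, heartbeat times, oxygen saturation and
    facial-action durations), extracts the stimulus-locked measures used in
    infant pain research (evoked-potential template magnitude after Woody
    alignment, automated peak-to-peak amplitude, EMG reflex RMS/duration/
    amplitude, windowed heart-rate and saturation change grids, facial
    durations), and discriminates the two conditions with a random forest
    re-implemented from scratch to bootstrap whole subjects so that paired
    observations stay together and out-of-bag predictions remain honest.
    Includes the companion statistics: Wilson score intervals, mid-P McNemar
    and exact binomial tests, ROC/AUC with subject-level bootstrap confidence
    intervals, DeLong's test for correlated ROC curves, Yates-corrected
    chi-square stratification and pairwise-complete Spearman correlation
    matrices, plus end-to-end experiment drivers and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    pROC,
    optparse
Config/testthat/edition: 3
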