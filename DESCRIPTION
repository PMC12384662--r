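Package: capseeg
Title: Micro-Capsule Networks for Single-Channel EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of epileptic seizures from single-channel
    electroencephalogram (EEG) recordings with a compact ("micro") capsule
    network. One-dimensional EEG is segmented with a fixed sliding window,
    each segment is expanded into a small two-dimensional matrix, and a
    capsule network (convolutional feature extractor, primary capsules,
    dynamic routing-by-agreement into label capsules) trained with a margin
    loss scores the probability that each clinical state (normal background,
    interictal, ictal) is present. Includes a reader for the Bonn ASCII EEG
    format, the 7:3 split with three-fold cross-validation evaluation
    protocol (accuracy, sensitivity, specificity), a time-interval sweep, a
    synthetic single-channel EEG generator for the three clinical states so
    the full pipeline runs without any download, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
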