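Package: pdwear
Title: Waist-Worn Accelerometry Pipeline for Parkinson's Disease Symptom Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of the on-device processing stack of a
    waist-worn inertial monitor for Parkinson's disease: a binary acquisition
    frame codec, Butterworth filtering and overlapped windowing, spectral and
    statistical feature extraction, RBF support-vector and threshold/tree
    classifiers, multi-rate aggregation of freezing-of-gait, bradykinetic
    gait, dyskinesia and ON/OFF motor-state outputs, a seeded synthetic
    parkinsonian-accelerometry simulator with ground-truth episode labels,
    episodic sensitivity/specificity evaluation, and storage/memory budget
    arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
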