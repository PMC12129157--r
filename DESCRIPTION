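Package: vocog
Title: Voice-Based Screening for Cognitive Decline from Short Conversations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens for cognitive decline from one-minute conversational
    speech using acoustic features alone. Audio is standardized to 16-bit
    16 kHz mono, cut into 5-second windows with a 1-second overlap, and each
    window is described by a 1028-value vector: a 768-dimensional speech
    embedding (pluggable encoder with a deterministic mock), 100 per-frame
    voicing probabilities, 100 per-frame fundamental-frequency values, and a
    60-value MFCC aggregate (per-coefficient max, mean, and mean delta).
    The window sequence is classified by a fully connected stack feeding a
    two-layer bidirectional LSTM and a sigmoid head, trained with binary
    cross-entropy against labels derived from Mini-Mental State Examination
    scores (23 or lower marks cognitive decline). Includes screening metrics
    (confusion counts, sensitivity, specificity, concordance AUC and ROC),
    a synthetic-prosody speech simulator for end-to-end testing, and a
    packaged fixture of a published 20-subject discrimination test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
LinkingTo:
    Rcpp
Config/testthat/edition: 3
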