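Package: poreformer
Title: Detecting Pore-Forming Proteins from Primary Sequence with a
    Convolutional Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting pore-forming proteins from amino-acid
    sequence alone. Provides dataset curation (length filtering, greedy
    identity clustering of positives, alignment-based purging of suspect
    negatives), three per-residue encodings (one-hot over a 28-symbol
    alphabet, Atchley 5-factor physicochemical, and their 33-channel
    combination), a small 1D convolutional neural network trained with
    mean-squared-error loss that scores sequences as pore-former
    probabilities, and an evaluation harness with stratified 80:20 splits,
    per-class ROC/AUC and held-out-family generalization counts. A seeded
    synthetic-sequence generator with plantable motif and composition signal
    makes every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
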