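Package: hotspotr
Title: Sequence-Based Prediction of Protein-Protein Interaction Hot-Spot Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interaction hot-spot residues from
    sequence alone. Computes a 173-value physicochemical descriptor for every
    residue of a FASTA chain (one-hot identity, relative-position quartile,
    19 literature-based amino-acid properties and their sliding-window
    averages), trains an extremely randomized trees classifier on labelled
    alanine-scanning data with a per-amino-acid stratified train/test split,
    applies a per-amino-acid probability-threshold correction fitted on a
    tuning set, and reports confusion-matrix metrics overall and by amino
    acid. Includes a synthetic-data generator that emulates the class
    structure of experimental alanine-scanning datasets for end-to-end
    testing.
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
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    nnet,
    optparse,
    pROC,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
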