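Package: cmorph
Title: Hard-to-Synthesize Structure Generation by Complexity-Bounded
    Molecular Morphing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates libraries of hard-to-synthesize small molecules by
    stochastic molecular morphing: a starting structure undergoes random
    elementary edits (add/remove/mutate an atom or a bond) until its
    structural complexity exceeds thresholds calibrated, per molecular-weight
    bin, from a reference library of synthetically accessible compounds.
    Four complexity indices (Bertz, Whitlock, Barone-Chanon, SMCM) provide
    the stop signal. Companion tools build labeled easy/hard training sets
    by the morphing, SAscore-threshold and dense-region strategies and
    benchmark them with a circular-fingerprint random-forest classifier
    (accuracy, sensitivity, specificity, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
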