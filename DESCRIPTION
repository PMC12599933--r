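Package: vteal
Title: Active Learning and Neural Classification of Venous Thromboembolism
    Imaging Reports
Version: 0.1.0
Authors@R:
    person("VTE", "Text Mining Group", email = "vteal@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying free-text venous-thromboembolism (VTE)
    imaging reports into seven anatomical classes with minimal labeling
    effort.  Implements pool-based active learning (random, least-confidence,
    margin, entropy, length-words, word-similarity and TF-IDF-similarity
    query strategies, plus combined word-similarity uncertainty sampling)
    over term-frequency, TF-IDF and dense document embeddings; four
    probabilistic classifier families (random forest, linear SVM, SVM with
    stochastic gradient descent, gradient boosting); small sequence
    classifiers (LSTM and single- or multi-kernel 1D convolutional networks,
    optionally with pretrained word vectors) trained with ADAM, early
    stopping and stratified cross-validation; multiclass precision / recall /
    F1 evaluation with corpus-composition and ICD-10 concordance summaries;
    and a deterministic template-based generator of synthetic radiology
    report corpora for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
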