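Package: raerank
Title: Listwise Ranking of Question-Snippet Pairs with Recursive Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate snippet answers for biomedical questions by
    classifying question-snippet pairs with a semi-supervised recursive
    autoencoder. Each question is concatenated with every candidate snippet
    extracted from its candidate documents; the token vectors of the pair are
    greedily composed into a binary tree by a recursive autoencoder, every
    internal node is classified for question-answer relatedness, and a
    listwise "ranking error" (the negative logarithm of a mean-average-
    precision-like sum over the relevant candidates) couples the candidates
    of a question during training. Includes the preprocessing pipeline
    (noun-phrase query formulation, snippet candidate enumeration, pair
    labelling), skip-gram embedding pretraining, a synthetic corpus
    generator with planted question-answer relations, and ranking evaluation
    utilities (average precision, paired batch comparisons, paired t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
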