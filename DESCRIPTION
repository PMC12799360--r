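Package: orthogo
Title: GO Annotation Transfer from Homologs and Orthogroups with
    Machine-Learning Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) annotations for query protein
    sequences by transferring terms from their k nearest homologs in an
    OrthoDB-style reference database (KNN), from the majority-voted
    orthogroup of those homologs (OG), and from the union of both
    (KNN+OG). Candidate terms are then verified with a trained per-term
    binary classifier (logistic regression, gradient boosting, or random
    forest) that filters, but never adds, terms. Includes a built-in
    Smith-Waterman search with BLOSUM62 scoring and Karlin-Altschul
    e-values, blast6 tabular hit import, CAFA-style precision / recall /
    accuracy / F-score and threshold-swept Fmax evaluation overall and
    per GO aspect, a k-sweep experiment driver, and a synthetic
    orthology benchmark generator so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    Rcpp,
    randomForest,
    stats,
    tibble,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
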