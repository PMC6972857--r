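Package: fflnet
Title: TF-miRNA Feed-Forward Loop Detection and Regulatory Network
    Analysis for Two-Group Expression Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential expression with an empirical-Bayes moderated
    t-statistic, correlation-based calling of signed transcription factor
    (TF) and microRNA (miRNA) regulation pairs against candidate prior
    lists, enumeration of coherent TF-miRNA-gene feed-forward loops (FFLs)
    in three categories (TF-repressed, TF-activated, miRNA-repressed),
    construction of subtype-specific regulatory networks with degree-based
    hub detection, hypergeometric enrichment of motif counts, and repeated
    stratified cross-validated random-forest evaluation of top FFLs as
    sample classifiers.  A synthetic-data generator plants fold-changes,
    signed correlations and ground-truth FFLs so the whole pipeline can be
    validated against a known truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
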