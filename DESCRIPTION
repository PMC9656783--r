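Package: genetriage
Title: Triangulating Disease Gene Candidates from Literature, Expression and Machine Learning Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for nominating disease-associated genes by
    combining three lines of evidence: dictionary-based gene-mention mining of an
    abstract corpus with an article-frequency filter, cross-dataset differential
    expression meta-analysis (Hedges' g effect sizes, DerSimonian-Laird
    random-effects pooling, Benjamini-Hochberg FDR), thresholded Pearson
    co-expression networks with hub ranking, overlap-ratio gene-set enrichment
    against GMT annotation collections, chromosomal-proximity comparison of gene
    lists, and tree-ensemble biomarker ranking (decision tree, random forest,
    extra-trees) with TMM normalization, stratified splits, Wilson confidence
    intervals and perturbation-based local surrogate explanations. A synthetic
    data generator with recorded ground truth makes every stage testable end to
    end without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    rpart,
    randomForest,
    ranger
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    metafor
Config/testthat/edition: 3
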