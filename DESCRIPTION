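Package: imcscope
Title: Single-Cell Imaging Mass Cytometry Analysis of Tissue Immune
    Microenvironments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for single-cell analysis of multiplexed
    imaging mass cytometry (IMC) data, developed around the immune
    microenvironment of chronic liver-allograft rejection. Provides a
    ground-truth synthetic tissue simulator, hot-pixel filtering and
    probability-map watershed segmentation, Phenograph-style
    kNN-Jaccard-Louvain meta-clustering with tSNE embedding, per-ROI
    quantification with Wilcoxon cohort comparisons, permutation-based spatial
    neighborhood interaction and avoidance testing, and PCA plus
    logistic-regression cohort modeling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    data.table,
    igraph,
    jsonlite,
    randomForest,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
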