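Package: tmekit
Title: Tumor Microenvironment Scoring and Mutational Signature Analysis
    for Bulk Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the tumor microenvironment (TME) from
    bulk transcriptomes and somatic mutation calls. Estimates immune-cell
    fractions by nu-support-vector regression against an LM22-style
    signature matrix, discovers TME clusters by consensus k-means with
    gap-statistic selection of the cluster number, derives a prognostic
    TMEscore (sum of log2 expression over hazard-decreasing genes minus
    the same sum over hazard-increasing genes, partitioned by univariate
    Cox coefficient sign), and runs the downstream analyses that link the
    score to mutation spectra (96-trinucleotide-context catalogs, KL-NMF
    signature extraction with cosine matching), tumor mutation burden,
    differential miRNA/mRNA/methylation features, survival screening,
    and immunotherapy-response prediction (DeLong AUC comparison).
    Includes synthetic-cohort generators with planted structure so every
    stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    randomForest,
    stats,
    survival,
    utils,
    withr
Suggests:
    Biostrings,
    cluster,
    jsonlite,
    limma,
    mclust,
    metafor,
    optparse,
    pROC,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
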