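Package: apneahub
Title: Hub-Gene Nomination from Breath-Hold Blood Transcriptome Time Courses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pinpointing breath-hold-responsive hub genes in small
    time-course blood transcriptome experiments. Implements low-count
    filtering, median-of-ratios size-factor normalization, selection of genes
    with step-wise increasing expression across timepoints, gene co-expression
    network construction and trimming, six-metric network centrality scoring
    aggregated into a sum rank score for hub nomination, a minimal running-sum
    gene-set enrichment engine with permutation-based significance, and
    one-way ANOVA with Tukey HSD post-hoc tests for replicate enzyme-activity
    assays. Includes a negative-binomial time-course simulator with planted
    monotone genes and a planted co-expression hub for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    fgsea,
    DESeq2
Config/testthat/edition: 3
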