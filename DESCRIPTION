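Package: methage
Title: Methylome Landscapes and Epigenetic Clocks from Bisulfite CGmap Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for age-focused analysis of whole-genome and targeted
    bisulfite sequencing data starting from per-cytosine CGmap methylation
    calls. Builds common-site methylation matrices at a coverage floor,
    computes global methylome descriptors (per-context means, level
    distributions, chromosome-binned tracks, Kolmogorov-Smirnov group
    comparisons, neighbor autocorrelation), metagene and repeat-body
    methylation profiles, per-site age-association statistics (Pearson
    correlation and one-way ANOVA with Benjamini-Hochberg adjustment),
    capture-panel region export, cohort structure views (PCA, Spearman
    sample clustering, top-variable-site clustering), and an elastic-net
    epigenetic clock with leave-one-out cross-validation. A synthetic
    cohort generator emits CGmap files with known ground truth so the
    whole pipeline can be exercised and validated without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    methods,
    jsonlite,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
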