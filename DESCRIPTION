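Package: rejuvr
Title: Quantifying Transcriptomic Rejuvenation in Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how strongly a systemic intervention
    reverses age-associated gene expression changes in single-nucleus
    RNA-seq data from heterochronic parabiosis designs. Provides
    quality-control filtering and log-normalisation for 10x-style sparse
    count matrices, per-cell-type Wilcoxon rank-sum differential
    expression with Benjamini-Hochberg correction, classification of
    aging differentially expressed genes as reversed or rescued by the
    intervention, reversal-ratio summaries, a coefficient-of-variation
    transcriptional-noise statistic, Pearson group-similarity, gene-set
    identity scoring, cross-subtype DEG module assignment, and a seeded
    negative-binomial simulator with planted effects and known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
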