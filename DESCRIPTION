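Package: coexbench
Title: Benchmarking Normalization and Transformation Workflows for RNA-Seq
    Coexpression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs gene coexpression networks from RNA-seq count data
    under combinatorial processing workflows (within-sample normalization:
    CPM/TPM/RPKM; between-sample normalization: quantile, TMM, upper
    quartile, and the counts-adjustment variants CTF and CUF; hyperbolic
    arcsine transformation; Pearson or Spearman correlation; CLR or
    weighted-topological-overlap network transformation) and evaluates the
    resulting networks against tissue-naive and tissue-aware functional
    gold standards derived from Gene Ontology annotations using
    log2(auPRC/prior), auROC, and precision at fixed recall. Includes
    paired workflow-comparison statistics with Benjamini-Hochberg
    correction, method-impact summaries, experimental-factor analyses,
    a resampling design, and a negative-binomial synthetic-corpus
    generator with planted coexpression modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
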