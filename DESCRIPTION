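Package: adaplast
Title: Adaptive and Maladaptive Gene Expression Plasticity from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gene-expression plasticity under an environmental
    stressor as adaptive or maladaptive by comparing plastic expression
    changes (treated versus untreated control lines) with evolved changes
    (selected versus control lines) in a two-line, two-treatment,
    two-timepoint bulk RNA-seq design. Implements the full supporting
    pipeline: counts-per-million expression filtering, trimmed-mean-of-
    M-values (TMM) library normalization, precision weights from a fitted
    mean-variance trend of log-CPM, gene-wise weighted linear models with
    empirical-Bayes variance moderation, Benjamini-Hochberg false discovery
    rate control, exact binomial sign-concordance tests, plasticity-magnitude
    comparisons between lines, Fisher exact term enrichment, and a
    negative-binomial count simulator with planted plastic/evolved effects
    and ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    optparse
Config/testthat/edition: 3
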