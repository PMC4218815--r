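Package: xenodeconv
Title: Cross-Species Expression Deconvolution for Xenograft Microarray
    Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for separating graft (human) and host (mouse) expression
    signals in xenograft microarray experiments where tissue at the invasion
    front is a species mixture. Implements probe-level cross-hybridization
    scoring and masking against the foreign-species transcriptome, quantile
    normalization and probeset summarization, per-line region-contrast
    differential expression with cross-line consensus, hypergeometric
    gene-set over-representation with membership-overlap term clustering,
    orthology-aware inference of tumor-host protein-protein crosstalk, and
    cross-platform fold-change concordance checks. Includes a synthetic-data
    generator with planted ground truth emulating a two-line, four-animal,
    three-region laser-microdissection design with dual hybridization of the
    mixed invasion-front samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    data.table,
    fgsea,
    igraph,
    jsonlite,
    limma,
    mclust,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
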