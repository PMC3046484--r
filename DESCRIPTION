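Package: crossortho
Title: Cross-Species Comparison of Global Gene-Expression Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing global gene-expression patterns between two
    species on microarray compendia: array-level quality filtering, ortholog
    probeset pairing by seeded local alignment of probe sequences, robust
    median/MAD normalization and cross-species matrix merging, principal
    component and tissue-correlation structure analysis, the correlation-of-
    correlations (corCor) conservation statistic with randomized nulls,
    variance-ranked window analysis of shared orthologs, and exact
    hypergeometric gene-list overlap tests. Includes a synthetic two-species
    data generator with planted tissue-specific and housekeeping signatures
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
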