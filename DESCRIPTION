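Package: coexppi
Title: Co-Expression Modules, Enrichment Tests and PPI Bottleneck Genes
    from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline from a gene-level RNA-seq count matrix to
    TPM-normalized expression, weighted gene co-expression modules with
    eigengene and module-trait statistics, tissue-specificity and gene-set
    enrichment via hypergeometric and size-matched randomization tests, and
    protein-protein-interaction bottleneck genes ranked by betweenness
    centrality. Includes a synthetic-data generator that plants co-expression
    modules, cell-type activity profiles, tissue-specific gene labels,
    differentially expressed genes and a bridge-node PPI graph, so that every
    stage of the analysis can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
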