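Package: glyconet
Title: Differential Co-Expression Networks of Glycolysis Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects altered transcriptional regulation of glycolysis from
    bulk RNA-seq counts by combining single-sample co-expression edge
    weights (linear interpolation to obtain network estimates for single
    samples, LIONESS) between transcription factors and glycolysis-related
    genes, empirical-Bayes moderated-t differential edge-weight testing
    with Benjamini-Hochberg correction, annotation of significant pairs
    against directed promoter-class and enhancer-class regulatory
    databases, and centrality-based selection of key regulators and
    target genes. Includes a synthetic-data generator with planted ground
    truth (negative-binomial counts with group-specific latent correlation
    structure, planted differentially expressed genes, and regulatory
    tables with controlled coverage) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
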