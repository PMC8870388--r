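Package: mirmultinet
Title: Multi-Layer miRNA-Gene-SNP-Drug Networks with Ontology Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping disease-associated microRNAs to
    experimentally validated target genes and assembling the evidence into
    multi-layer pharmacogenomic networks. Reads tabular miRNA-target,
    miRNA-disease, drug-target and SNP-gene records together with a disease
    ontology (OBO or edge list), filters interactions by experimental
    evidence type, performs hypergeometric over-representation analysis
    with Bonferroni control, computes Wang graph-based semantic similarity
    between enriched ontology terms, clusters terms hierarchically, and
    builds per-cluster gene-miRNA-SNP-drug networks with degree statistics,
    top-k rankings and Cytoscape-compatible GraphML/SIF export. Includes a
    synthetic-data generator with planted enrichment signal for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
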