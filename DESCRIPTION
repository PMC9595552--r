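Package: funhop
Title: Compartment-Aware KEGG Pathway Analysis with Functional Homolog
    Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Expands multi-gene nodes of KEGG KGML pathway maps so every
    functional homolog is displayed, assigns each gene product a consensus
    subcellular localization by voting over experimental (SubCellBarCode,
    Human Protein Atlas) and predicted (BUSCA) sources, overlays signed
    differential-expression scores onto the expanded networks, and splits
    metabolic pathways into mitochondrial and non-mitochondrial variants
    with connectivity diagnostics.  Exports annotated KGML, GraphML and
    node-attribute tables for display in Cytoscape.  Ships seeded synthetic
    generators for pathways, localization tables in all three source
    dialects, and differential-expression tables so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    igraph,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
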