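Package: netpharm
Title: Network Pharmacology Target Identification for Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, offline pipeline for network-pharmacology target
    identification in multi-herb traditional-medicine formulas: ADME
    screening of chemical ingredients by oral bioavailability and
    drug-likeness, construction of herb-ingredient-target tripartite
    networks with herb-target projection and shared-target histograms,
    differential expression calling on two-group log-expression matrices,
    three-way intersection of disease genes, differentially expressed genes
    and network targets, hypergeometric over-representation analysis with
    Benjamini-Hochberg false discovery rate control under dual backgrounds,
    and from-scratch Gene Set Enrichment Analysis with phenotype
    permutation. Seeded synthetic-data generators with full truth records
    make every stage verifiable end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    limma,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
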