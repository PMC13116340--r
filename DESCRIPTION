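Package: dockpanel
Title: Cross-Docking Affinity Panels, Kinase Selectivity Statistics, and
    Node-Based Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing compound-by-target cross-docking affinity
    matrices in developmental-toxicology screening. Aggregates replicate
    docking scores with quality-control flags, screens for outlying cells
    under an additive two-way model, and assesses clustering stability by
    bootstrap. Provides paired and class-stratified tests of target
    selectivity with Bonferroni control and paired-design effect sizes,
    per-compound selectivity (SI) and specificity (SPI) indices, and a
    combined off-target risk ranking. Includes cross-tool phosphosite
    consensus voting with casein kinase 1 substrate-motif scanning, exact
    Venn decomposition and staged integration of gene-symbol sets, and a
    rule-based decision tree mapping affinity profiles of Hedgehog-pathway
    modulators onto node-specific craniofacial phenotype hypotheses. A
    synthetic-data module generates replicate score tables, tool-prediction
    tables, motif-bearing protein sequences, and gene universes with known
    structure so that every stage is testable without docking runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
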