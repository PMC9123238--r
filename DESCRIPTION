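Package: hsfkit
Title: Gene-Family Cataloguing, Reconciliation and Regulatory-Network
    Analysis for Heat Shock Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for large-scale comparative analysis of the plant heat
    shock transcription factor (Hsf) gene family and its chaperone (Hsp)
    targets: domain-hit based family cataloguing with isoform
    deduplication and per-species summary statistics; conserved-motif
    state tables and Dollo (single-gain, multiple-loss) trajectories on a
    species tree; LCA-mapping reconciliation of rooted gene trees against
    a species tree with per-branch duplication and loss counts; duplicate
    type classification (singleton, dispersed, proximal, tandem,
    WGD/segmental) with dynamic-programming collinear block chaining and
    chi-square enrichment; regulatory target networks, Pearson-correlation
    co-expression networks with hub statistics, hypergeometric term
    enrichment and Venn partitions; heat shock element (HSE) consensus
    scanning of promoters; subgenome retention bookkeeping for a
    triplicated pan-genome; and seeded synthetic-data generators with
    machine-readable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
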