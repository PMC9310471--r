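Package: nichecrosstalk
Title: Ligand-Receptor Crosstalk Inference for the Aging Neurogenic Niche
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cell-cell communication between sender and receiver cell
    types from single-cell RNA-seq count matrices. Implements quality-control
    filtering, library-size log-normalization, Wilcoxon rank-sum differential
    expression with Bonferroni correction, enumeration of ligand-receptor gene
    pairs against an annotated gene-pair reference database, pair power scoring
    (sum of log2 fold changes or product of mean expression), noisy-OR evidence
    aggregation, cluster-label permutation significance, functional-term
    restriction and per-cell-type-pair summaries, together with preranked gene
    set enrichment analysis (ES/NES/FDR), hypergeometric term enrichment and
    gene-set activation z-scores. Ships a seeded negative-binomial simulator
    that plants aged-microglia, memory T cell and endothelial signals to
    exercise the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    igraph,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
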