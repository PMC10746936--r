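Package: dicoexnet
Title: Differential Co-Expression Network Analysis for Two-Phenotype
    Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for network-medicine analysis of
    two-phenotype (disease versus control) transcriptome studies:
    per-study differential expression with Benjamini-Hochberg control and
    fold-change filtering, cross-study intersection of differentially
    expressed genes, condition-specific Spearman co-expression networks
    thresholded by a critical-correlation cutoff (mean + 1.96 sd of the
    correlation distribution) and a differential-correlation criterion
    |SCCd - SCCh| > 0.5, greedy-modularity module detection with density
    and correlation-pattern summaries, Kaplan-Meier/log-rank prognostic
    evaluation of module scores, local drug-signature reversal ranking,
    and TF-IDF literature-novelty scoring. A synthetic-data generator
    with planted differentially expressed genes, a planted differential
    co-expression module, matched survival data, a drug-signature
    library and an abstract corpus makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
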