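Package: phx
Title: Phage-Host Dual Transcriptomics: Temporal Classes, Host DEGs,
    Enrichment and Cross-Genome Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dual-organism (bacteriophage plus
    bacterial host) expression time series over a one-step infection
    cycle: a synthetic-data generator with planted temporal classes,
    differential-expression structure and correlation pairs; ingest and
    housekeeping-gene normalization of intensity matrices; assignment of
    phage ORFs to early/middle/late kinetic classes with drug-condition
    cross-validation; per-timepoint host differential-expression calling
    (fold change, one-way ANOVA, Benjamini-Hochberg FDR); stage-resolved
    Fisher exact pathway enrichment and functional-class ratio tables;
    and hard-thresholded signed Pearson co-expression networks between
    phage and host genes with degree (K-score) hotspot ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
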