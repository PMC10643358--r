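Package: landqtl
Title: Marker-Trait Associations, LD-Based QTL Intervals and Candidate
    Genes in Landrace Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association analysis for inbred landrace diversity
    panels phenotyped over multiple seasons. Provides marker quality control,
    pairwise linkage-disequilibrium (r2) estimation with LOESS decay curves
    and half-decay distance, the effective number of independent tests for
    Bonferroni correction, general-linear-model association scans with
    population-structure covariates, LD-block clumping of significant markers
    into marker-trait-association QTL (MTA-QTL) intervals, multi-environment
    stability annotation, high-density multi-trait regions with a
    days-to-heading covariate re-test, and candidate-gene interval queries
    with a transcripts-per-million expression filter. A synthetic-data
    generator with planted causal loci supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
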