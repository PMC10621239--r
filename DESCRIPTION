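Package: svpopkit
Title: Ensemble Structural-Variant Merging and Population Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale structural-variant (SV) analysis from
    multi-caller call sets: ingestion of symbolic-ALT/BND VCFs, single-linkage
    consensus merging under breakpoint and size tolerances with 2-of-3 caller
    support and calibration against curated reference SVs, genic-context and
    impact annotation, Fisher-exact allele-frequency divergence between
    populations with FDR control, standardized kinship and PCA, LD pruning,
    EMMAX-style mixed-model association, and windowed read-depth
    presence/absence deletion detection. Includes a synthetic-cohort
    generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
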