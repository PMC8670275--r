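Package: methylRI
Title: Longitudinal DNA Methylation Stability via Reference Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies CpG sites by the temporal stability of their DNA
    methylation level in dense repeated-measures array data. Computes
    within-individual reference intervals (the difference between the 95th
    and 5th percentiles of the methylation percentage across timepoints),
    assigns CpGs to stable, dynamic and hyperdynamic categories, flags
    between-individual variable (CDMV) CpGs, applies probe-level quality
    filters (missingness, SNP overlap, cell-type-composition association
    tested by nested-model ANOVA), characterizes categories by CpG-context
    and genic annotation with fractional counting, and quantifies each
    category's likelihood of being an EWAS marker via Fisher odds ratios
    and DerSimonian-Laird random-effects meta-analysis with Cochran's Q
    heterogeneity. A synthetic-cohort generator emulates the two-individual,
    two-tissue, 24-timepoint study design so the whole pipeline runs and is
    testable without access to restricted individual-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
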