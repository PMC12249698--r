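Package: panelval
Title: Analytical and Clinical Validation Toolkit for a Comprehensive Genomic Profiling Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements the analytical- and clinical-validation computations
    of a large (1021-gene) hybrid-capture tumor profiling assay for FFPE tissue
    and plasma cell-free DNA: compartment-specific variant positivity filtering,
    tumor mutational burden (TMB) scoring, microsatellite instability (MSI)
    classification, sample-level percent loss-of-heterozygosity (gLOH) from
    allele-specific copy number, actionability tiering, and the validation
    statistics (PPA/NPA, exact binomial confidence intervals, limit-of-detection
    profiles, Pearson concordance, QC gating) that summarize assay performance.
    A synthetic-data layer emulates reference standards under binomial read
    sampling, clinical cohorts with configured biomarker prevalences, paired
    tissue/plasma samples under a ctDNA-fraction dilution model, and SNP
    BAF/logR profiles under a purity/ploidy allele-specific copy-number model,
    so every downstream stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
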