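Package: ctdnaconcord
Title: Matched Plasma and Urine ctDNA Variant Filtering, Classification
    and Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for matched liquid-biopsy cohorts in which
    each patient contributes an annotated somatic variant callset from
    blood plasma and one from urine. Implements a sequential three-stage
    somatic variant filter cascade (confidence, common-variant and
    predicted-deleterious filters), ACMG/AMP five-class impact
    classification from evidence codes, AMP/ASCO/CAP four-tier clinical
    significance assignment, variant allele fraction binning, per-patient
    shared/exclusive variant concordance with recovery rates, per-gene
    aggregation, a pathogenic-variant presence matrix, and the cohort
    statistics used for cell-free DNA concentration comparisons (Spearman
    rank correlation, Wilcoxon signed-rank, chi-square). A seeded
    synthetic cohort generator emits matched annotated VCF pairs with
    planted filter fates and known ground truth so the whole pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
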