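Package: aluedit
Title: A-to-I RNA Editing Detection, Editing Index, and Cohort Survival Analysis
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls candidate A-to-I RNA editing sites from aligned RNA-seq
    (SAM or per-base pileup tables) as A-to-G / T-to-C mismatches against a
    reference genome, removes known SNPs, applies tiered edit-ratio/depth
    filters, annotates sites against gene models and Alu elements, and
    computes the genome-wide A-to-I editing index (AEI), the sum of
    edit/read ratios over retained sites. Includes patient-cohort
    statistics (Spearman correlation with Gaussian-approximation p-values,
    Kaplan-Meier estimation, log-rank testing, median survival, paired and
    unpaired t-tests, covariate panels) and a fully seeded synthetic-data
    generator producing reference sequences with embedded Alu elements and
    gene models, per-sample pileups with known editing rates, and survival
    cohorts whose hazard increases with true AEI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
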