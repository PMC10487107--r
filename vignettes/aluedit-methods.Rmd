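---
title: "aluedit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aluedit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

ADAR enzymes convert adenosine to inosine in double-stranded RNA.
Because inosine pairs like guanosine, reverse transcription reads an
edited adenosine as `G`: in aligned RNA-seq, A-to-I editing is visible
as `A>G` mismatches against the reference on the strand carrying the
`A`, and as `T>C` on the opposite strand. The dominant substrate is
dsRNA formed by inverted Alu repeats, so most true sites cluster in Alu
intervals. The same mismatch signature is produced by genomic
polymorphism (hence the known-SNP filter) and by sequencing error
(hence ratio/depth thresholds).

# The pipeline model

## Site calling

For every pileup column with reference base `A` and at least one `G`
read, the package emits a candidate site with `edit_type = "AG"` and
strand `+`; reference `T` with at least one `C` emits `TC`/`-`. The edit
count is the mismatch-base count; the total is the full column depth, so
unrelated mismatches at the same column dilute the ratio rather than
being discarded. No other mismatch class can ever become a site, a
position can yield at most one site (the reference base fixes the only
admissible class), and reference-`N` columns are skipped. Strand is
assigned purely from the mismatch class; gene-model strand is never
consulted, and annotation never changes a call.

## Category tiers

Three filters on the per-site edit/read ratio `r` and depth:

| tier | thresholds |
|---|---|
| `all` | ≥ 1 edit, ≥ 1 read |
| `standard` | r ≥ 0.05 and ≥ 5 reads |
| `stringent` | r ≥ 0.25 and ≥ 10 reads |

Boundaries are **inclusive** by default. The tier definitions exist in
two published phrasings that disagree about inclusivity at the boundary;
we implement the ≥ form and expose `strict = TRUE` to switch every
threshold to `>`, so both readings are testable. The `all` tier's
"≥ 1 edit per read" phrasing is interpreted as "at least one edit and at
least one read". The thresholds are the only sequencing-noise guard —
no explicit error model is subtracted at detection time.

## The A-to-I editing index

For one sample, `AEI = Σ r_i` over the sites that survive SNP filtering
and a category filter. It is additive over disjoint partitions of the
genome, monotone under adding sites, and non-increasing as the category
tightens — properties the test suite asserts. The headline index uses
the `standard` tier (the tier described immediately before the index is
defined in the source analysis); all three tiers are always computed.
"Expressed genome" is operationalized as any position with at least one
mapped read; there is no additional expression floor beyond the category
read minima. Whether the index should sum all sites or only Alu sites is
ambiguous in the source; the default sums all retained sites, and an
Alu-only variant is a one-line filter on the annotated site table.

## Annotation

Sites are annotated by point overlap against per-class interval sets
(interval-tree queries via `GenomicRanges`; a brute-force linear scan is
the test oracle). When a position overlaps several classes the fixed
precedence is `utr3 > utr5 > exonic_cds > noncoding_or_RNA > intronic >
intergenic` — UTR status is the most specific call, and any interval of
a noncoding/RNA gene annotates as `noncoding_or_RNA` regardless of
feature kind. Overlap ignores strand (no strand rule is given for
annotation in the source). `in_alu` is independent of the region class.

## Cohort statistics

* **Spearman with Gaussian p**: `r` is the Pearson correlation of
  average ranks; the two-sided p-value uses the classical large-sample
  form `z = r√(n−1)` because that approximation is named verbatim in
  the source figure captions. The t-approximation is available behind a
  flag. Constant vectors are an error (undefined correlation), and
  fewer than 4 complete pairs refuse to compute.
* **Dichotomization at 50**: the source wording ("> 50" vs "< 50")
  leaves equality unassigned; the split must be total, so ties go to the
  high group by default (`equal_to_cutoff = "low"` flips it) and the
  choice is echoed in the run metadata.
* **Kaplan–Meier / log-rank**: implemented directly — the product-limit
  estimator with censoring reducing the risk set without a step, and the
  Mantel–Cox statistic with the hypergeometric variance
  `d(n−d)·n_a·n_b / (n²(n−1))` accumulated over pooled distinct event
  times. The `survival` package is an independent oracle in the tests,
  never the implementation. The source analyzes time to death with no
  mention of censoring; all-events is therefore the faithful special
  case, but an event flag is supported throughout. Median survival is
  the smallest observed time with `S(t) ≤ 0.5`, reported as not-reached
  (`NA`) when the curve never gets there.
* **Phase comparison**: Welch (unequal-variance) unpaired t-test —
  pooled vs Welch is unspecified in the source, and Welch is the safer
  default — plus a paired t-test on within-patient differences.
  Zero-variance degenerate cases are resolved by rule rather than
  returning `NaN`: zero spread with zero mean difference gives p = 1,
  zero spread with a nonzero difference gives p = 0.
* **Covariate panel**: per covariate, Spearman r against AEI
  (pairwise-complete; rows with < 4 complete pairs are flagged rather
  than dropped silently) and low/high-group mean ± SD with a Welch
  t-test. No multiple-testing correction is applied by default because
  the source reports per-row significance only.

# The synthetic-data generator

The real cohort (23 melanoma patients, paired pre-/on-therapy biopsies,
controlled-access sequencing) cannot ship with the package, so the
generator emits a stated stand-in world, and its defaults *are* that
statement:

* **Reference**: one uniform-random 30 kb contig. Alu intervals
  (default 40, 250–350 bp) are placed one per equal-width bin, so they
  are mutually disjoint but freely overlap gene structures; genes
  (default 10, ~30% noncoding) are laid left to right with 2–4 exons,
  150–600 bp introns, and UTRs embedded in the terminal exons of coding
  genes.
* **Truth sites**: 200 A/T positions, 80% inside Alu (editing
  concentrates in Alu repeats), never at a SNP, with rates drawn from
  Beta(0.8, 4) — right-skewed, mean ≈ 0.17, substantial mass below the
  `standard` ratio floor, which is what makes the tier filters
  non-trivial.
* **Pileups**: depth ~ NegBinom(mean 50, size 5); the edited-base count
  at a truth site is Binomial(depth, q′) with the error-folded rate
  q′ = q(1−e) + (1−q)e/3; every other wrong base is Binomial(depth,
  e/3) with e = 0.001. SNPs (default 50, 60% heterozygous) are
  transition variants at A/T positions — alt fraction 0.5 or 1.0 — so an
  unfiltered SNP is indistinguishable from a strong editing site; the
  SNP-exclusion acceptance criterion checks exactly this leak.
* **Cohort**: pre-therapy AEI ~ Gamma with mean 48 and sd 27 (the
  published cohort moments; Gamma keeps the support positive at this
  coefficient of variation), on-therapy AEI = pre + N(11, 20) (matching
  the published on-therapy mean 59 and sd ≈ 35 while keeping phases
  correlated within patients). Death time is exponential with rate
  (1/60 per week)·exp(0.75·z) where z is the standardized AEI. The
  slope 0.75 was calibrated once by Monte Carlo (n = 2·10⁵) so the
  population Spearman between AEI and death time is ≈ −0.5, and then
  frozen. ADAR expression is 500 + 10·AEI + N(0, 200) (positive
  correlation with AEI); mutation, neoantigen and neopeptide loads and
  the GZMA/PRF1 cytolytic inputs are log-normal and independent of AEI,
  mirroring the null covariate findings.
* **Full pipeline coupling**: in `run_full_pipeline`, patients receive a
  Gamma(mean 1.45, sd 0.8) multiplier on all truth-site rates (on-phase:
  + N(0.33, 0.6)), so the *measured* per-patient AEI spans roughly
  10–110 and the cohort's survival is generated from the per-patient
  true AEI sums. This is a calibration guide to the published scale,
  not an equality claim.

What the generator does **not** emulate: read-level artifacts
(duplicates, strand protocol, quality-score structure, mapping bias),
hg19-scale genomes, hyper-editing clusters, clonal tumor architecture,
or any coupling between editing and the immunogenicity covariates. A
green recovery test therefore establishes that the pipeline's
arithmetic and filters are correct under the stated model — not that
the biological effect sizes are realistic beyond the published moments
used as inputs.

# Numerical and testing choices

* **Coordinates** are 1-based and closed everywhere inside the package —
  the Bioconductor convention — with conversion only at file boundaries
  (BED is 0-based half-open on disk; VCF, GTF-like gene models and the
  site tables are 1-based). One internal convention, converted once,
  eliminates off-by-one drift.
* **Quality gates** for the SAM path default to base quality ≥ 20 and
  mapping quality ≥ 20. The source states none; these are conventional
  values for editing callers and are recorded in the run manifest so
  results are reproducible.
* **Site-table round-trips** are exact: the ratio column is validated on
  read and recomputed as `edits/reads`, so `read(write(x)) == x`
  bit-for-bit.
* **AEI recovery tolerance**: the acceptance band is
  3·√(Σ q′(1−q′)/d) with the error-adjusted q′ summed over *all*
  emitted A/T positions (truth sites plus error-only positions, SNPs
  excluded) and realized depths — the exact mean and variance of the
  `all`-tier AEI under the generator model. Comparing against the
  truth-rate sum alone would be biased by precisely the sequencing-error
  term q′ exists to fold in.
* **Stochastic acceptance checks** run at fixed seeds with
  pre-registered bands: the Spearman-sign recovery requires a negative
  estimate in ≥ 95% of 200 cohort replicates; the log-rank power at the
  default effect size was measured once at the frozen defaults and
  stored as a regression band (0.60 ± 0.15); the slope-0 null requires
  the rejection rate to sit inside the binomial 99% band around 0.05.
* **Determinism**: every generator call seeds its own stream derived
  from the master seed; rerunning the full pipeline with the same config
  produces byte-identical content files (the manifest timestamp is the
  only exception, and the determinism test strips it).

# Known limitations

Detection operates at pileup granularity, so read-level evidence
(per-read phasing, duplicate structure) is unavailable; hyper-editing
clusters and ADAR motif context are out of scope; the log-rank
implementation is two-group only (no stratification, no Cox model); the
covariate panel performs pairwise deletion rather than imputation; and
the CLI is a thin wrapper over the R API rather than a workflow engine.
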