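# aluedit

Detection and quantification of A-to-I RNA editing from aligned RNA-seq,
with cohort-level survival analysis.

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA —
predominantly in inverted Alu repeats — and inosine base-pairs like
guanosine, so editing appears in sequencing data as `A>G` mismatches on
the plus strand and `T>C` on the minus strand. `aluedit` is for
transcriptomics researchers who want to quantify per-sample global
editing and relate it to clinical outcome. It implements:

- **Site calling** from a SAM file or a per-base pileup table: a
  candidate site is any position where the reference base is `A` with at
  least one `G` read (`AG`, strand `+`) or `T` with at least one `C`
  (`TC`, strand `-`). No other mismatch class is ever called.
- **Known-SNP filtering** (a polymorphism mimics editing exactly) and
  three tiered category filters on the edit/read ratio
  r = edits / total reads:
  `all` (≥ 1 edit, ≥ 1 read), `standard` (r ≥ 0.05, reads ≥ 5),
  `stringent` (r ≥ 0.25, reads ≥ 10); a strict-inequality switch is
  available.
- **The A-to-I editing index (AEI)** per sample and tier:

  AEI = Σ_sites r_i,

  the sum of edit/read ratios over all retained sites across the
  expressed genome.
- **Annotation** of each site against gene models (3'/5' UTR, CDS exon,
  noncoding/RNA gene, intron, intergenic) and an Alu interval set.
- **Cohort statistics**: Spearman correlation with the Gaussian
  approximation p-value (z = r·√(n−1)), AEI dichotomization at a cutoff
  (default 50), Kaplan–Meier product-limit curves, the Mantel–Cox
  log-rank test, median survival, paired/unpaired Welch t-tests between
  therapy phases, the cytolytic score √(GZMA·PRF1), and an
  immunogenicity covariate panel.
- **A fully seeded synthetic-data generator** producing every input the
  pipeline consumes (reference with embedded Alu elements and gene
  structures, transition SNPs, per-sample pileups with Beta-distributed
  true editing rates, and a cohort whose death hazard is log-linear in
  standardized true AEI) together with ground-truth tables.

## Worked example

```r
library(aluedit)

cfg   <- simulation_config(101L)          # seeded synthetic world
world <- simulate_reference(cfg)
truth <- simulate_true_sites(cfg, world$reference, world$alu, world$snps)
pu    <- simulate_sample_pileup(truth, cfg, sample_seed = 1001L,
                                world$reference, world$snps)
prof  <- profile_sample(pu, world$reference,
                        world$snps[, c("contig", "position")],
                        sample_id = "patient01", phase = "pre")
prof
#> sample_profile 'patient01' (phase pre)
#>   sites called 444, SNP-removed 50, retained 394
#>   AEI: all 37.470 | standard 32.481 | stringent 18.537
```

444 mismatch positions were called on the 30 kb synthetic contig; all 50
known SNPs were among them and were removed; summing edit/read ratios
over the 394 retained sites gives the per-tier AEI (the error-only
sites inflate the permissive `all` tier, which is why the `standard`
tier is the headline index). Cohort-level analysis on a simulated
23-patient cohort:

```r
co  <- simulate_cohort(cfg)$cohort
rep <- cohort_report(co)      # cutoff 50, ties to the high group
```

prints, via its components:

```
Spearman(AEI_pre, survival): r = -0.592, p = 0.0055 (n = 23)
log-rank chi2 = 10.301, p = 0.0013; median survival low 104.5 vs high 21.3 weeks
phase comparison: pre 45.2 +/- 25.4, on 53.1 +/- 23.4; unpaired p = 0.28, paired p = 0.02
```

Higher editing predicts shorter survival (the generator's hazard
increases with true AEI), and the low-AEI group's median survival
exceeds the high-AEI group's — the qualitative pattern the package is
designed to detect.

## Command line

```sh
inst/exec/aluedit run --out out/ --seed 7         # full simulated pipeline
inst/exec/aluedit detect --pileup s.tsv --reference ref.fa \
    --snps snps.vcf --out sites.tsv
inst/exec/aluedit annotate --sites sites.tsv --genes genes.tsv \
    --alu alu.bed --out annotated.tsv --summary regions.tsv
inst/exec/aluedit aei --sites annotated.tsv --out aei.tsv
inst/exec/aluedit cohort --cohort cohort.csv --aei aei.tsv --out report/
```

`run` writes `reference.fasta`, `alu.bed`, `genes.tsv`, `snps.vcf`,
per-sample pileups and site tables, `aei.tsv`, `cohort.csv`, the cohort
report TSVs, ground-truth tables under `truth/`, and `manifest.json`
(per-stage counts, seeds, and every threshold the run used). Reruns with
the same config are byte-identical apart from the manifest timestamp.

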