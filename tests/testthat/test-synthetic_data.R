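test_that("simulation_config validates fields and rejects unknown keys", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(1L, bogus_knob = 3), "bogus_knob")
  expect_error(simulation_config(1L, fraction_in_alu = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(1L, hazard_baseline = -1), "hazard")
  cfg <- simulation_config(5L, n_alu = 10L)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_alu, 10L)
  expect_equal(cfg$cohort_n, 23L)          # published cohort size
  expect_equal(c(cfg$aei_mean, cfg$aei_sd), c(48, 27))
})

test_that("simulate_reference is deterministic and respects counts", {
  cfg <- simulation_config(7L, contig_length = 8000L, n_alu = 10L,
                           n_genes = 3L, n_snps = 30L)
  w1 <- simulate_reference(cfg)
  w2 <- simulate_reference(cfg)
  expect_identical(as.character(w1$reference), as.character(w2$reference))
  expect_identical(w1$alu, w2$alu)
  expect_identical(w1$snps, w2$snps)

  expect_equal(nrow(w1$alu), 10L)
  expect_true(all(w1$alu$end > w1$alu$start))
  ## Alu intervals are mutually disjoint
  expect_true(all(w1$alu$start[-1L] > head(w1$alu$end, -1L)))
  expect_equal(nrow(w1$snps), 30L)
  expect_equal(anyDuplicated(w1$snps$position), 0L)
  ## SNPs are transition mimics at A/T positions
  bases <- strsplit(as.character(w1$reference[[1L]]), "")[[1L]]
  expect_true(all(bases[w1$snps$position] %in% c("A", "T")))
  expect_true(all(w1$snps$alt == ifelse(w1$snps$ref == "A", "G", "C")))
  ## UTRs lie inside exons of their gene
  utr <- w1$genes[feature %in% c("utr5", "utr3")]
  for (i in seq_len(nrow(utr))) {
    ex <- w1$genes[gene_id == utr$gene_id[i] & feature == "exon"]
    expect_true(any(ex$start <= utr$start[i] & utr$end[i] <= ex$end))
  }

  none <- simulate_reference(simulation_config(7L, contig_length = 8000L,
                                               n_alu = 0L, n_genes = 0L,
                                               n_snps = 0L))
  expect_equal(nrow(none$alu), 0L)
  expect_equal(nrow(none$genes), 0L)
})

test_that("simulate_true_sites places sites by Alu fraction, off SNPs", {
  cfg <- simulation_config(8L, contig_length = 10000L, n_alu = 12L,
                           n_genes = 4L, n_edit_sites = 120L,
                           fraction_in_alu = 1.0)
  w <- simulate_reference(cfg)
  tr <- simulate_true_sites(cfg, w$reference, w$alu, w$snps)
  expect_equal(nrow(tr), 120L)
  expect_true(all(tr$in_alu))
  expect_equal(length(intersect(tr$position, w$snps$position)), 0L)
  expect_true(all(tr$edit_type == ifelse(tr$ref == "A", "AG", "TC")))
  expect_true(all(tr$rate >= 0 & tr$rate <= 1))

  zero <- simulate_true_sites(
    simulation_config(8L, n_edit_sites = 0L), w$reference, w$alu, w$snps)
  expect_equal(nrow(zero), 0L)
})

test_that("Beta(1,1) editing rates are uniform (KS at n = 2000)", {
  cfg <- simulation_config(9L, contig_length = 30000L, n_edit_sites = 2000L,
                           edit_rate_shape1 = 1, edit_rate_shape2 = 1,
                           fraction_in_alu = 0.5, n_snps = 0L)
  w <- simulate_reference(cfg)
  tr <- simulate_true_sites(cfg, w$reference, w$alu, w$snps)
  ks <- suppressWarnings(stats::ks.test(tr$rate, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("pileup simulation: degenerate rate-1 site and binomial recovery", {
  cfg <- simulation_config(10L, contig_length = 400L, n_genes = 0L,
                           n_alu = 1L, n_edit_sites = 1L, n_snps = 0L,
                           base_error_rate = 0, fraction_in_alu = 0)
  w <- simulate_reference(cfg)
  tr <- simulate_true_sites(cfg, w$reference, w$alu, w$snps)
  tr$rate <- 1.0
  pu <- simulate_sample_pileup(tr, cfg, 123L, w$reference, w$snps)
  col <- pu[pos == tr$position]
  alt <- if (tr$ref == "A") col$G else col$C
  expect_equal(alt, col$depth)              # every read edited
  ## and with error 0, off-site columns are pure reference
  off <- pu[pos != tr$position]
  bases <- strsplit(as.character(w$reference[[1L]]), "")[[1L]]
  refcount <- mapply(function(p, r) off[pos == p][[r]],
                     off$pos, bases[off$pos])
  expect_equal(as.integer(refcount), off$depth)

  ## mean observed ratio at a rate-0.3 site across 300 resimulations
  tr$rate <- 0.3
  ratios <- vapply(1:300, function(i) {
    p <- simulate_sample_pileup(tr, cfg, 5000L + i, w$reference, w$snps)
    col <- p[pos == tr$position]
    (if (tr$ref == "A") col$G else col$C) / col$depth
  }, numeric(1L))
  ## SE of the mean ratio at NB depth ~50: conservative bound 3 * se
  se <- sqrt(0.3 * 0.7 / cfg$mean_depth / 300) * 1.3
  expect_lt(abs(mean(ratios) - 0.3), 3 * se)
})

test_that("heterozygous SNPs emit ~50% alt and are removed by the filter", {
  cfg <- simulation_config(11L, contig_length = 2000L, n_genes = 0L,
                           n_alu = 2L, n_edit_sites = 10L, n_snps = 15L,
                           snp_het_fraction = 1.0, mean_depth = 40)
  w <- simulate_reference(cfg)
  tr <- simulate_true_sites(cfg, w$reference, w$alu, w$snps)
  pu <- simulate_sample_pileup(tr, cfg, 77L, w$reference, w$snps)
  snp_cols <- pu[pos %in% w$snps$position]
  alt <- ifelse(snp_cols$ref == "A", snp_cols$G, snp_cols$C)
  ## pooled alt fraction near 0.5 (binomial, ~600 reads)
  expect_lt(abs(sum(alt) / sum(snp_cols$depth) - 0.5), 0.08)
  prof <- profile_sample(pu, w$reference, w$snps[, c("contig", "position")])
  expect_equal(length(intersect(prof$sites$position, w$snps$position)), 0L)
})

test_that("simulate_cohort hits the published scale and couplings", {
  cfg <- simulation_config(12L)
  reps <- 40L
  means <- numeric(reps)
  for (i in seq_len(reps)) {
    co <- simulate_cohort(cfg, seed = 4000L + i)$cohort
    means[i] <- mean(co[phase == "pre", aei])
  }
  ## CLT band around the configured mean 48 (sd 27, n 23)
  expect_lt(abs(mean(means) - 48), 3 * 27 / sqrt(23 * reps))

  out <- simulate_cohort(cfg, seed = 4242L)
  co <- out$cohort
  expect_equal(nrow(co), 2L * cfg$cohort_n)
  expect_true(all(co$survival_weeks >= 0))
  expect_true(all(co$event == 1L))           # no censoring by default
  expect_equal(co[phase == "pre", aei], out$truth$true_pre_aei)
  ## survival equals truth death time when uncensored
  expect_equal(co[phase == "pre", survival_weeks], out$truth$death_time)
  ## covariates independent of AEI: slope-0 null handled in acceptance

  expect_error(simulate_cohort(cfg, per_patient_true_aei = 1:5),
               "cohort_n")
})

test_that("pipeline recovery: standard tier finds >=90% of strong sites", {
  cfg <- simulation_config(13L, contig_length = 12000L, n_alu = 15L,
                           n_genes = 5L, n_edit_sites = 100L,
                           mean_depth = 40)
  w <- simulate_reference(cfg)
  tr <- simulate_true_sites(cfg, w$reference, w$alu, w$snps)
  pu <- simulate_sample_pileup(tr, cfg, 999L, w$reference, w$snps)
  prof <- profile_sample(pu, w$reference, w$snps[, c("contig", "position")])
  std <- apply_category(prof$sites, "standard")
  strong <- tr[tr$rate >= 0.1, ]
  recovered <- mean(strong$position %in% std$position)
  expect_gte(recovered, 0.9)
})
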