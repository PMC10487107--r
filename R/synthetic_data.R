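## Seeded synthetic-data generator.
##
## Emulates the controlled-access tumor RNA-seq the real analysis
## consumed, at pileup granularity: a uniform-random contig carrying
## non-overlapping Alu intervals and gene structures, truth editing sites
## with Beta-distributed rates concentrated in Alu elements, per-position
## negative-binomial depth, binomial editing plus uniform sequencing
## error, transition SNPs (the filter's confounders), and a patient
## cohort whose death hazard is log-linear in standardized true AEI while
## ADAR expression tracks AEI linearly. Everything is deterministic for a
## fixed seed. Cohort scale parameters default to the published cohort
## moments (n = 23, AEI mean 48, sd 27; on-therapy 59 +/- 35).

#' Build a validated simulation configuration
#'
#' Every knob of the generator, with defaults chosen as a realistic
#' desk-scale stand-in (see the methods vignette for rationale). `seed`
#' is mandatory; all downstream generator calls derive their streams
#' from it.
#'
#' @param seed Integer master seed (mandatory).
#' @param ... Overrides for any default field (unknown names error).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed, ...) {
  if (missing(seed) || !is_count(seed))
    abort_format("simulation_config requires an integer seed")
  cfg <- list(
    seed = as.integer(seed),
    contig_name = "chrS",
    contig_length = 30000L,
    n_genes = 10L,
    n_alu = 40L,
    alu_length_range = c(250L, 350L),
    n_edit_sites = 200L,
    edit_rate_shape1 = 0.8,       # Beta(0.8, 4): right-skewed, mean ~0.17
    edit_rate_shape2 = 4,
    fraction_in_alu = 0.8,
    mean_depth = 50,
    depth_dispersion = 5,         # negative-binomial size
    base_error_rate = 0.001,
    n_snps = 50L,
    snp_het_fraction = 0.6,
    cohort_n = 23L,
    aei_mean = 48,                # published pre-therapy cohort moments
    aei_sd = 27,
    on_aei_shift_mean = 11,       # on-therapy mean 59, sd ~35
    on_aei_shift_sd = 20,
    hazard_baseline = 1 / 60,     # per week
    hazard_slope = 0.75,          # per standardized-AEI unit;
                                  # population Spearman(AEI, T) ~ -0.5
    censor_time = Inf,            # paper-faithful: all deaths observed
    adar_intercept = 500,
    adar_slope = 10,
    adar_noise_sd = 200,
    mutation_meanlog = log(250),  mutation_sdlog = 1,
    neoantigen_meanlog = log(150), neoantigen_sdlog = 1,
    neopeptide_meanlog = log(400), neopeptide_sdlog = 1,
    gzma_meanlog = log(500),      gzma_sdlog = 0.8,
    prf1_meanlog = log(500),      prf1_sdlog = 0.8,
    patient_effect_mean = 1.45,   # per-patient editing-rate multiplier
    patient_effect_sd = 0.8,
    on_effect_shift_mean = 0.33,
    on_effect_shift_sd = 0.6)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    abort_format("unknown simulation_config field(s): %s",
                 paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(is_count(cfg$seed), "seed must be an integer")
  chk(is_count(cfg$contig_length, positive = TRUE),
      "contig_length must be a positive integer")
  chk(is_count(cfg$n_genes) && is_count(cfg$n_alu) &&
        is_count(cfg$n_edit_sites) && is_count(cfg$n_snps),
      "n_genes, n_alu, n_edit_sites, n_snps must be nonnegative integers")
  for (f in c("fraction_in_alu", "snp_het_fraction", "base_error_rate"))
    chk(is_number(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
        sprintf("%s must lie in [0, 1]", f))
  chk(is_number(cfg$mean_depth) && cfg$mean_depth > 0,
      "mean_depth must be > 0")
  chk(is_number(cfg$depth_dispersion) && cfg$depth_dispersion > 0,
      "depth_dispersion must be > 0")
  chk(is_number(cfg$edit_rate_shape1) && cfg$edit_rate_shape1 > 0 &&
        is_number(cfg$edit_rate_shape2) && cfg$edit_rate_shape2 > 0,
      "edit-rate Beta parameters must be > 0")
  chk(is_number(cfg$hazard_baseline) && cfg$hazard_baseline > 0,
      "hazard_baseline must be > 0")
  chk(is_number(cfg$hazard_slope), "hazard_slope must be finite")
  chk(is_count(cfg$cohort_n, positive = TRUE), "cohort_n must be >= 1")
  chk(is_number(cfg$aei_mean) && cfg$aei_mean > 0 &&
        is_number(cfg$aei_sd) && cfg$aei_sd > 0,
      "aei_mean and aei_sd must be > 0")
  chk(length(cfg$alu_length_range) == 2L &&
        cfg$alu_length_range[1] <= cfg$alu_length_range[2] &&
        cfg$alu_length_range[1] >= 1,
      "alu_length_range must be an increasing pair of positive lengths")
  if (length(errs))
    abort_format("invalid simulation config:\n  - %s",
                 paste(errs, collapse = "\n  - "))
  invisible(cfg)
}

#' Simulate the reference world: contig, Alu intervals, gene models, SNPs
#'
#' The contig is uniform-random over ACGT. Alu intervals are placed one
#' per equal-width bin (mutually disjoint, some landing inside genes).
#' Gene structures (exons, introns, UTRs inside terminal exons for coding
#' genes; roughly 30% of genes noncoding) are laid left to right without
#' overlap. SNPs are transition variants at A/T positions (`A>G` on ref A,
#' `T>C` on ref T) so that an unfiltered SNP is indistinguishable from an
#' editing site.
#'
#' @param config A `sim_config`.
#' @return `list(reference = DNAStringSet, alu =, genes =, snps =)`.
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  L <- config$contig_length
  ctg <- config$contig_name
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  reference <- Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""),
                                                 ctg))

  ## Alu placement: one interval per bin, guaranteed disjoint
  alu <- data.table(contig = character(), start = integer(),
                    end = integer(), label = character())
  if (config$n_alu > 0L) {
    bin <- L %/% config$n_alu
    max_len <- config$alu_length_range[2]
    if (bin <= max_len)
      abort_format(paste("cannot fit %d Alu intervals of up to %d bp in a",
                         "%d bp contig; reduce n_alu or enlarge the contig"),
                   config$n_alu, max_len, L)
    len <- sample(seq(config$alu_length_range[1], max_len),
                  config$n_alu, replace = TRUE)
    offset <- vapply(seq_len(config$n_alu), function(i)
      sample.int(bin - len[i], 1L), integer(1L))
    start <- (seq_len(config$n_alu) - 1L) * bin + offset
    alu <- data.table(contig = ctg, start = as.integer(start),
                      end = as.integer(start + len - 1L),
                      label = paste0("AluSim", seq_len(config$n_alu)))
  }

  ## gene structures, laid left to right
  genes <- data.table(gene_id = character(), gene_type = character(),
                      feature = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character())
  if (config$n_genes > 0L) {
    rows <- list()
    cursor <- 1L
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("GENE%03d", g)
      gtype <- if (runif(1) < 0.3) "noncoding_or_RNA" else "protein_coding"
      gstrand <- sample(c("+", "-"), 1L)
      cursor <- cursor + sample(100:300, 1L)      # intergenic gap
      n_ex <- sample(2:4, 1L)
      ex_len <- sample(150:300, n_ex, replace = TRUE)
      in_len <- sample(200:600, max(n_ex - 1L, 0L), replace = TRUE)
      need <- sum(ex_len) + sum(in_len)
      if (cursor + need > L)
        abort_format(paste("gene structures exceed the contig at gene %d;",
                           "enlarge contig_length or reduce n_genes"), g)
      pos <- cursor
      for (e in seq_len(n_ex)) {
        ex_start <- pos; ex_end <- pos + ex_len[e] - 1L
        rows[[length(rows) + 1L]] <- data.table(
          gene_id = gid, gene_type = gtype, feature = "exon",
          contig = ctg, start = ex_start, end = ex_end, strand = gstrand)
        if (gtype == "protein_coding") {
          if (e == 1L)
            rows[[length(rows) + 1L]] <- data.table(
              gene_id = gid, gene_type = gtype, feature = "utr5",
              contig = ctg, start = ex_start,
              end = ex_start + 49L, strand = gstrand)
          if (e == n_ex)
            rows[[length(rows) + 1L]] <- data.table(
              gene_id = gid, gene_type = gtype, feature = "utr3",
              contig = ctg, start = ex_end - 79L,
              end = ex_end, strand = gstrand)
        }
        pos <- ex_end + 1L
        if (e < n_ex) {
          rows[[length(rows) + 1L]] <- data.table(
            gene_id = gid, gene_type = gtype, feature = "intron",
            contig = ctg, start = pos, end = pos + in_len[e] - 1L,
            strand = gstrand)
          pos <- pos + in_len[e]
        }
      }
      cursor <- pos
    }
    genes <- rbindlist(rows)
  }

  ## transition SNPs at A/T positions
  snps <- data.table(contig = character(), position = integer(),
                     ref = character(), alt = character(),
                     allele_fraction = numeric(), het = logical())
  if (config$n_snps > 0L) {
    at_pos <- which(bases %in% c("A", "T"))
    if (length(at_pos) < config$n_snps)
      abort_format("not enough A/T positions for %d SNPs", config$n_snps)
    p <- sort(sample(at_pos, config$n_snps))
    het <- rep(FALSE, config$n_snps)
    het[sample.int(config$n_snps,
                   round(config$snp_het_fraction * config$n_snps))] <- TRUE
    snps <- data.table(
      contig = ctg, position = as.integer(p), ref = bases[p],
      alt = ifelse(bases[p] == "A", "G", "C"),
      allele_fraction = ifelse(het, 0.5, 1.0), het = het)
  }
  list(reference = reference, alu = alu, genes = genes, snps = snps)
}

#' Draw ground-truth editing sites
#'
#' Places `n_edit_sites` sites at A/T positions, the configured fraction
#' inside Alu intervals, never at a SNP position, with per-site editing
#' rates drawn from the configured Beta distribution.
#'
#' @param config A `sim_config`.
#' @param reference `DNAStringSet` from [simulate_reference()].
#' @param alu_intervals Alu interval table.
#' @param snps Optional SNP table whose positions are excluded.
#' @return Truth `data.table`: `contig`, `position`, `ref`, `edit_type`,
#'   `strand`, `rate`, `in_alu`.
#' @export
simulate_true_sites <- function(config, reference, alu_intervals,
                                snps = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 2L))
  ctg <- names(reference)[1L]
  bases <- strsplit(as.character(reference[[ctg]]), "")[[1L]]
  L <- length(bases)
  in_alu_mask <- rep(FALSE, L)
  alu_intervals <- as.data.table(alu_intervals)
  if (nrow(alu_intervals))
    for (i in seq_len(nrow(alu_intervals)))
      in_alu_mask[alu_intervals$start[i]:alu_intervals$end[i]] <- TRUE
  banned <- if (!is.null(snps) && nrow(as.data.table(snps)))
    as.data.table(snps)$position else integer()
  at <- which(bases %in% c("A", "T"))
  at <- setdiff(at, banned)
  pool_in <- at[in_alu_mask[at]]
  pool_out <- at[!in_alu_mask[at]]
  n <- config$n_edit_sites
  if (n == 0L)
    return(data.table(contig = character(), position = integer(),
                      ref = character(), edit_type = character(),
                      strand = character(), rate = numeric(),
                      in_alu = logical()))
  n_in <- round(config$fraction_in_alu * n)
  n_out <- n - n_in
  if (length(pool_in) < n_in || length(pool_out) < n_out)
    abort_format(paste("not enough eligible A/T positions (%d in-Alu, %d",
                       "outside) for %d truth sites; enlarge the contig"),
                 length(pool_in), length(pool_out), n)
  pos <- sort(c(if (n_in) sample(pool_in, n_in) else integer(),
                if (n_out) sample(pool_out, n_out) else integer()))
  rate <- rbeta(n, config$edit_rate_shape1, config$edit_rate_shape2)
  data.table(contig = ctg, position = as.integer(pos), ref = bases[pos],
             edit_type = ifelse(bases[pos] == "A", "AG", "TC"),
             strand = ifelse(bases[pos] == "A", "+", "-"),
             rate = rate, in_alu = in_alu_mask[pos])
}

#' Error-adjusted per-site alternative-base rate
#'
#' The probability that a read shows the edited/alternative base at a
#' position with true rate `rate`, folding in a uniform per-base
#' sequencing error `e` (miscalls spread evenly over the 3 wrong bases):
#' `rate * (1 - e) + (1 - rate) * e / 3`.
#'
#' @param rate True editing (or allele) rate.
#' @param base_error_rate Per-base error probability.
#' @return Adjusted rate(s).
#' @export
adjusted_edit_rate <- function(rate, base_error_rate) {
  rate * (1 - base_error_rate) + (1 - rate) * base_error_rate / 3
}

#' Simulate one sample's pileup
#'
#' Per position: depth ~ NegBinom(`mean_depth`, `depth_dispersion`); at a
#' truth site the edited base count is Binomial(depth, error-adjusted
#' rate); at a SNP the alternative base follows its allele fraction
#' (0.5 het, 1.0 hom); every other wrong base is Binomial(depth,
#' `base_error_rate`/3). Zero-depth positions are omitted.
#'
#' @param truth Truth site table from [simulate_true_sites()].
#' @param config A `sim_config`.
#' @param sample_seed Integer seed for this sample's stream.
#' @param reference `DNAStringSet`.
#' @param snps SNP table from [simulate_reference()] (or `NULL`).
#' @param rate_multiplier Per-sample multiplier on truth rates (rates are
#'   capped at 1); used to endow patients with distinct global editing
#'   levels.
#' @return Pileup `data.table` (`contig`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T`, `depth`).
#' @export
simulate_sample_pileup <- function(truth, config, sample_seed,
                                   reference, snps = NULL,
                                   rate_multiplier = 1) {
  validate_sim_config(config)
  set.seed(as.integer(sample_seed))
  ctg <- names(reference)[1L]
  bases <- strsplit(as.character(reference[[ctg]]), "")[[1L]]
  L <- length(bases)
  depth <- rnbinom(L, size = config$depth_dispersion, mu = config$mean_depth)
  e3 <- config$base_error_rate / 3

  ## per-position alternative-base probability (G for ref A, C for ref T)
  alt_prob <- rep(e3, L)
  truth <- as.data.table(truth)
  if (nrow(truth)) {
    q <- pmin(truth$rate * rate_multiplier, 1)
    alt_prob[truth$position] <- adjusted_edit_rate(q, config$base_error_rate)
  }
  if (!is.null(snps)) {
    snps <- as.data.table(snps)
    if (nrow(snps))
      alt_prob[snps$position] <- adjusted_edit_rate(
        snps$allele_fraction, config$base_error_rate)
  }

  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  transition_of <- c(A = "G", C = "T", G = "A", T = "C")
  for (b in c("A", "C", "G", "T")) {
    idx <- which(bases == b & depth > 0L)
    if (!length(idx)) next
    alt_b <- transition_of[[b]]
    others <- setdiff(c("A", "C", "G", "T"), c(b, alt_b))
    n_alt <- rbinom(length(idx), depth[idx],
                    if (b %in% c("A", "T")) alt_prob[idx] else e3)
    n_o1 <- rbinom(length(idx), depth[idx], e3)
    n_o2 <- rbinom(length(idx), depth[idx], e3)
    n_ref <- pmax(depth[idx] - n_alt - n_o1 - n_o2, 0L)
    counts[idx, alt_b] <- n_alt
    counts[idx, others[1L]] <- n_o1
    counts[idx, others[2L]] <- n_o2
    counts[idx, b] <- n_ref
  }
  keep <- which(depth > 0L)
  pu <- data.table(contig = ctg, pos = keep, ref = bases[keep],
                   A = counts[keep, "A"], C = counts[keep, "C"],
                   G = counts[keep, "G"], T = counts[keep, "T"])
  pu[, depth := A + C + G + T]
  pu[depth > 0L][]
}

#' Simulate the patient cohort
#'
#' Pre-therapy true AEIs are supplied or drawn from a Gamma distribution
#' matching the configured mean/sd target; death time is exponential with
#' rate `hazard_baseline * exp(hazard_slope * (AEI - mean)/sd)` so higher
#' AEI means shorter survival; ADAR expression is linear in AEI plus
#' Gaussian noise; mutation/neoantigen/neopeptide loads and the cytolytic
#' inputs are log-normal and independent of AEI. On-therapy AEI is the
#' pre value plus a Gaussian shift. Optional administrative censoring at
#' `censor_time`.
#'
#' @param config A `sim_config`.
#' @param per_patient_true_aei Optional numeric vector of length
#'   `cohort_n` of pre-therapy AEIs (e.g. measured from simulated
#'   pileups).
#' @param seed Stream seed (defaults to a child of `config$seed`).
#' @param per_patient_on_aei Optional on-therapy AEIs (paired).
#' @return `list(cohort = data.table (2 rows per patient), truth =
#'   data.table)`.
#' @export
simulate_cohort <- function(config, per_patient_true_aei = NULL,
                            seed = derive_seed(config$seed, 3L),
                            per_patient_on_aei = NULL) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  n <- config$cohort_n
  m <- config$aei_mean; s <- config$aei_sd
  pre_aei <- if (!is.null(per_patient_true_aei)) {
    if (length(per_patient_true_aei) != n)
      abort_format("per_patient_true_aei must have length cohort_n = %d", n)
    as.numeric(per_patient_true_aei)
  } else {
    rgamma(n, shape = (m / s)^2, scale = s^2 / m)
  }
  on_aei <- if (!is.null(per_patient_on_aei)) {
    as.numeric(per_patient_on_aei)
  } else {
    pmax(pre_aei + rnorm(n, config$on_aei_shift_mean,
                         config$on_aei_shift_sd), 0)
  }
  z <- (pre_aei - m) / s
  hazard <- config$hazard_baseline * exp(config$hazard_slope * z)
  death_time <- rexp(n, rate = hazard)
  if (is.finite(config$censor_time)) {
    event <- as.integer(death_time <= config$censor_time)
    surv <- pmin(death_time, config$censor_time)
  } else {
    event <- rep(1L, n)
    surv <- death_time
  }
  adar <- function(aei) pmax(config$adar_intercept +
                               config$adar_slope * aei +
                               rnorm(n, 0, config$adar_noise_sd), 1)
  adar_pre <- adar(pre_aei)
  adar_on <- adar(on_aei)
  mut <- rlnorm(n, config$mutation_meanlog, config$mutation_sdlog)
  neoag <- rlnorm(n, config$neoantigen_meanlog, config$neoantigen_sdlog)
  neopep <- rlnorm(n, config$neopeptide_meanlog, config$neopeptide_sdlog)
  gzma <- rlnorm(n, config$gzma_meanlog, config$gzma_sdlog)
  prf1 <- rlnorm(n, config$prf1_meanlog, config$prf1_sdlog)
  pid <- sprintf("P%03d", seq_len(n))
  one_phase <- function(ph, aei, adar_v) data.table(
    patient_id = pid, phase = ph, aei = aei,
    survival_weeks = surv, event = event,
    adar_expr = adar_v, gzma_expr = gzma, prf1_expr = prf1,
    mutation_load = mut, neoantigen_load = neoag, neopeptide_load = neopep)
  cohort <- rbind(one_phase("pre", pre_aei, adar_pre),
                  one_phase("on", on_aei, adar_on))
  cohort[, cytolytic_score := sqrt(gzma_expr * prf1_expr)]
  setorder(cohort, patient_id, -phase)   # pre before on per patient
  truth <- data.table(patient_id = pid, true_pre_aei = pre_aei,
                      true_on_aei = on_aei, hazard = hazard,
                      death_time = death_time, event = event)
  list(cohort = cohort[], truth = truth)
}
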