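## Independent oracles and fixture builders shared across test files.
## Everything here is deliberately written without reusing the package's
## code paths (per-read walkers, linear scans, textbook formulas).

library(data.table)

## ---- random reference / reads / SAM ---------------------------------------

oracle_random_reference <- function(len, name = "chrT") {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  list(name = name, bases = bases,
       dss = Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""),
                                               name)))
}

## one read: start (1-based), cigar as list of (op, len), seq built from
## the reference with random mismatches (and arbitrary bases in clips)
oracle_random_read <- function(refchars, mismatch_rate = 0.08) {
  L <- length(refchars)
  span <- sample(15:40, 1L)
  start <- sample.int(max(L - span - 5L, 1L), 1L)
  ops <- list()
  u <- runif(1)
  if (u < 0.25 && span > 12) {          # internal deletion
    m1 <- sample(5:(span - 7L), 1L)
    dl <- sample(1:3, 1L)
    ops <- list(c("M", m1), c("D", dl), c("M", span - m1 - dl))
  } else if (u < 0.4) {                 # leading soft clip
    ops <- list(c("S", sample(2:5, 1L)), c("M", span))
  } else {
    ops <- list(c("M", span))
  }
  seq <- character(0)
  gpos <- start
  for (op in ops) {
    n <- as.integer(op[2])
    if (op[1] == "M") {
      b <- refchars[gpos:(gpos + n - 1L)]
      mm <- runif(n) < mismatch_rate
      b[mm] <- vapply(b[mm], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1L))
      seq <- c(seq, b)
      gpos <- gpos + n
    } else if (op[1] == "D") {
      gpos <- gpos + n
    } else if (op[1] == "S") {
      seq <- c(seq, sample(c("A", "C", "G", "T"), n, replace = TRUE))
    }
  }
  list(start = start, ops = ops, seq = paste(seq, collapse = ""))
}

oracle_write_sam <- function(reads, ref, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$name, length(ref$bases)))
  recs <- vapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    cig <- paste0(vapply(r$ops, function(o) paste0(o[2], o[1]),
                         character(1L)), collapse = "")
    sprintf("r%03d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
            i, ref$name, r$start, cig, r$seq,
            strrep("I", nchar(r$seq)))
  }, character(1L))
  writeLines(c(hdr, recs), path)
  path
}

## brute-force per-read, per-position pileup walker (the detection oracle)
oracle_pileup <- function(reads, ref) {
  L <- length(ref$bases)
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (r in reads) {
    rpos <- 1L
    gpos <- r$start
    for (op in r$ops) {
      n <- as.integer(op[2])
      if (op[1] == "M") {
        for (k in seq_len(n)) {
          b <- substring(r$seq, rpos, rpos)
          counts[b, gpos] <- counts[b, gpos] + 1L
          rpos <- rpos + 1L; gpos <- gpos + 1L
        }
      } else if (op[1] == "D") {
        gpos <- gpos + n
      } else if (op[1] == "S") {
        rpos <- rpos + n
      }
    }
  }
  covered <- which(colSums(counts) > 0L)
  data.table(contig = ref$name, pos = covered, ref = ref$bases[covered],
             A = counts["A", covered], C = counts["C", covered],
             G = counts["G", covered], T = counts["T", covered],
             depth = colSums(counts)[covered])
}

## enumerate expected edit sites straight from an oracle pileup
oracle_sites <- function(opu) {
  ag <- opu[ref == "A" & G >= 1L,
            .(contig, position = pos, edit_type = "AG",
              edit_count = G, total_reads = depth)]
  tc <- opu[ref == "T" & C >= 1L,
            .(contig, position = pos, edit_type = "TC",
              edit_count = C, total_reads = depth)]
  out <- rbind(ag, tc)
  setorder(out, contig, position)
  out[]
}

## ---- interval / stats oracles ---------------------------------------------

## linear-scan point overlap: returns indices of intervals covering p
oracle_point_overlap <- function(p, starts, ends) {
  which(starts <= p & p <= ends)
}

## classical no-ties rank formula
oracle_spearman_rank_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## brute-force Mantel-Cox accumulation over pooled event times
oracle_logrank_chisq <- function(ta, ea, tb, eb) {
  times <- c(ta, tb); events <- c(ea, eb)
  ga <- c(rep(TRUE, length(ta)), rep(FALSE, length(tb)))
  O <- E <- V <- 0
  for (t in sort(unique(times[events == 1]))) {
    n <- sum(times >= t); na <- sum(times >= t & ga)
    d <- sum(times == t & events == 1)
    da <- sum(times == t & events == 1 & ga)
    O <- O + da
    E <- E + d * na / n
    if (n > 1) V <- V + d * (n - d) * na * (n - na) / (n^2 * (n - 1))
  }
  (O - E)^2 / V
}

## ---- site-table builders ---------------------------------------------------

make_sites <- function(edits, reads, contig = "chrT",
                       position = seq_along(edits), edit_type = "AG") {
  et <- rep(edit_type, length.out = length(edits))
  data.table(
    contig = contig, position = as.integer(position),
    edit_type = et, strand = ifelse(et == "AG", "+", "-"),
    edit_count = as.integer(edits), total_reads = as.integer(reads),
    edit_ratio = edits / reads, snp_filtered = NA,
    region_class = NA_character_, in_alu = NA)
}

random_sites <- function(n, contig = "chrT") {
  reads <- sample(1:60, n, replace = TRUE)
  edits <- vapply(reads, function(r) sample.int(r, 1L), integer(1L))
  et <- sample(c("AG", "TC"), n, replace = TRUE)
  make_sites(edits, reads, contig = contig,
             position = sample.int(1e6, n), edit_type = et)
}

## a small deterministic annotation world used across annotation tests:
## one coding gene, one noncoding gene, two Alu elements (one inside the
## coding gene's intron, one intergenic)
fixture_annotation_world <- function() {
  genes <- data.table(
    gene_id = c("GC1", "GC1", "GC1", "GC1", "GC1", "GNC", "GNC", "GNC"),
    gene_type = c(rep("protein_coding", 5L), rep("noncoding_or_RNA", 3L)),
    feature = c("exon", "utr5", "intron", "exon", "utr3",
                "exon", "intron", "exon"),
    contig = "chrT",
    start = c(101L, 101L, 201L, 501L, 581L, 1001L, 1101L, 1301L),
    end   = c(200L, 140L, 500L, 600L, 600L, 1100L, 1300L, 1400L),
    strand = c(rep("+", 5L), rep("-", 3L)))
  alu <- data.table(contig = "chrT",
                    start = c(301L, 801L), end = c(400L, 900L),
                    label = c("AluIntronic", "AluIntergenic"))
  list(genes = genes, alu = alu)
}

## small simulation config for fast end-to-end tests
small_sim_overrides <- function(seed = 11L) {
  list(seed = seed, contig_length = 6000L, n_genes = 3L, n_alu = 8L,
       n_edit_sites = 60L, n_snps = 20L, cohort_n = 6L, mean_depth = 30)
}
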