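## Readers/writers for every external format the pipeline touches.
##
## Internal convention: 1-based, closed intervals; point positions are
## 1-based. Files keep their native conventions: VCF POS and the site-table
## `position` column are 1-based (identity), BED is 0-based half-open
## (start shifted by +1 on read, -1 on write). Gene-model TSVs are 1-based
## inclusive, like GTF.

#' Read a FASTA reference
#'
#' Sequences are uppercased; `N` is allowed. One record per header.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-token
#'   of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_format("FASTA file not found: %s", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) abort_format("malformed FASTA '%s': %s",
                                     path, conditionMessage(e)))
  if (length(seqs) == 0L) abort_format("FASTA '%s' contains no records", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  empty <- Biostrings::width(seqs) == 0L
  if (any(empty))
    abort_format("FASTA record '%s' has an empty sequence",
                 names(seqs)[which(empty)[1L]])
  if (anyDuplicated(names(seqs)))
    abort_format("FASTA '%s' has duplicated record name '%s'",
                 path, names(seqs)[duplicated(names(seqs))][1L])
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read known-SNP positions from a VCF
#'
#' Only CHROM and POS are consumed (genotype fields are ignored);
#' multi-allelic rows contribute one position; duplicates collapse.
#'
#' @param path Path to an uncompressed VCF (v4.x).
#' @return `data.table` with columns `contig`, `position` (1-based),
#'   unique rows, file order of first appearance.
#' @export
read_vcf_positions <- function(path) {
  if (!file.exists(path)) abort_format("VCF file not found: %s", path)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body_idx) == 0L)
    return(data.table(contig = character(), position = integer()))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    abort_format("VCF '%s' line %d has fewer than 2 columns",
                 path, body_idx[bad[1L]])
  contig <- vapply(fields, `[[`, character(1L), 1L)
  pos_chr <- vapply(fields, `[[`, character(1L), 2L)
  pos_num <- suppressWarnings(as.numeric(pos_chr))
  bad <- which(is.na(pos_num) | pos_num != as.integer(pos_num))
  if (length(bad))
    abort_format("VCF '%s' line %d: non-integer POS '%s'",
                 path, body_idx[bad[1L]], pos_chr[bad[1L]])
  pos <- as.integer(pos_num)
  unique(data.table(contig = contig, position = pos))
}

#' Write SNP positions to a minimal VCF
#'
#' @param snps `data.frame` with `contig`, `position` (1-based) and
#'   optionally `ref`, `alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path) {
  stopifnot_cols(snps, c("contig", "position"), "SNP table")
  ref <- if ("ref" %in% names(snps)) snps$ref else rep("N", nrow(snps))
  alt <- if ("alt" %in% names(snps)) snps$alt else rep(".", nrow(snps))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       snps$contig, as.integer(snps$position), ref, alt), con)
  invisible(path)
}

#' Read Alu (or any) intervals from BED
#'
#' BED is 0-based half-open on disk; returned intervals are 1-based closed.
#' Overlapping intervals are preserved, never merged.
#'
#' @param path Path to a BED3+ file.
#' @return `data.table` with `contig`, `start`, `end` (1-based closed),
#'   `label` (BED name column, or `NA`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_format("BED file not found: %s", path)
  if (file.size(path) == 0L)
    return(data.table(contig = character(), start = integer(),
                      end = integer(), label = character()))
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   abort_format("malformed BED '%s': %s",
                                path, conditionMessage(e)))
  if (any(GenomicRanges::width(gr) <= 0L))
    abort_format("BED '%s' has an interval with start >= end", path)
  data.table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    label  = if (!is.null(gr$name)) as.character(gr$name)
             else rep(NA_character_, length(gr)))
}

#' Write 1-based closed intervals as BED
#'
#' @param intervals `data.frame` with `contig`, `start`, `end` (1-based
#'   closed) and optional `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot_cols(intervals, c("contig", "start", "end"), "interval table")
  dt <- as.data.table(intervals)
  out <- data.table(dt$contig, as.integer(dt$start) - 1L, as.integer(dt$end))
  if ("label" %in% names(dt)) out[, name := dt$label]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---- pileups ---------------------------------------------------------------

#' Read a precomputed pileup table
#'
#' Expected TSV columns: `contig`, `pos` (1-based), `ref`, `A`, `C`, `G`,
#' `T` (per-base read counts).
#'
#' @param path Path to the TSV.
#' @return A pileup `data.table` (columns as above, plus `depth`).
#' @export
read_pileup_tsv <- function(path) {
  if (!file.exists(path)) abort_format("pileup file not found: %s", path)
  pu <- fread(path, sep = "\t", header = TRUE)
  stopifnot_cols(pu, c("contig", "pos", "ref", "A", "C", "G", "T"), "pileup")
  cnt <- as.matrix(pu[, c("A", "C", "G", "T")])
  if (any(cnt < 0))
    abort_format("pileup '%s': negative count at row %d",
                 path, which(rowSums(cnt < 0) > 0)[1L])
  pu[, depth := A + C + G + T]
  pu[]
}

#' Write a pileup table
#' @param pileup Pileup `data.table` (see [read_pileup_tsv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  stopifnot_cols(pileup, c("contig", "pos", "ref", "A", "C", "G", "T"),
                 "pileup")
  fwrite(as.data.table(pileup)[, .(contig, pos, ref, A, C, G, T)],
         path, sep = "\t")
  invisible(path)
}

#' Build a pileup from a SAM file
#'
#' Converts the SAM to a temporary BAM and runs a quality-gated pileup.
#' Bases below `min_base_quality` and reads below `min_mapping_quality`
#' are excluded; deletions and reference skips contribute nothing.
#'
#' @param path Path to a SAM file with `@SQ` header lines.
#' @param reference `DNAStringSet` covering every contig in the SAM header.
#' @param min_base_quality,min_mapping_quality Phred gates (default 20/20).
#' @return A pileup `data.table` as from [read_pileup_tsv()].
#' @export
pileup_from_sam <- function(path, reference,
                            min_base_quality = 20L,
                            min_mapping_quality = 20L) {
  if (!file.exists(path)) abort_format("SAM file not found: %s", path)
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = TRUE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  unknown <- setdiff(names(hdr), names(reference))
  if (length(unknown))
    abort_format("SAM contig '%s' absent from the reference", unknown[1L])
  pp <- Rsamtools::PileupParam(
    max_depth = 100000L,
    min_base_quality = as.integer(min_base_quality),
    min_mapq = as.integer(min_mapping_quality),
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE)
  res <- as.data.table(Rsamtools::pileup(bam, pileupParam = pp))
  if (nrow(res) == 0L)
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), A = integer(), C = integer(),
                      G = integer(), T = integer(), depth = integer()))
  res <- res[nucleotide %in% c("A", "C", "G", "T")]
  res[, nucleotide := as.character(nucleotide)]
  wide <- dcast(res, seqnames + pos ~ nucleotide,
                value.var = "count", fill = 0L)
  for (b in c("A", "C", "G", "T"))
    if (!b %in% names(wide)) wide[, (b) := 0L]
  pu <- data.table(contig = as.character(wide$seqnames),
                   pos = as.integer(wide$pos),
                   A = as.integer(wide$A), C = as.integer(wide$C),
                   G = as.integer(wide$G), T = as.integer(wide$T))
  pu[, ref := reference_base(reference, contig, pos)]
  pu[, depth := A + C + G + T]
  setcolorder(pu, c("contig", "pos", "ref", "A", "C", "G", "T", "depth"))
  setorder(pu, contig, pos)
  pu[]
}

#' Read alignments (SAM) or a precomputed pileup (TSV)
#'
#' Dispatches on file extension: `.sam` goes through [pileup_from_sam()],
#' anything else through [read_pileup_tsv()].
#'
#' @inheritParams pileup_from_sam
#' @return A pileup `data.table`.
#' @export
read_alignments_or_pileup <- function(path, reference = NULL,
                                      min_base_quality = 20L,
                                      min_mapping_quality = 20L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    if (is.null(reference))
      abort_format("a reference is required to pile up a SAM file")
    pileup_from_sam(path, reference, min_base_quality, min_mapping_quality)
  } else {
    read_pileup_tsv(path)
  }
}

## look up reference bases for (contig, position) vectors
reference_base <- function(reference, contig, position) {
  out <- character(length(contig))
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg)
    if (!ctg %in% names(reference))
      abort_format("contig '%s' absent from the reference", ctg)
    s <- as.character(reference[[ctg]])
    p <- position[idx]
    if (any(p < 1L | p > nchar(s)))
      abort_format("position outside contig '%s' (length %d)", ctg, nchar(s))
    out[idx] <- substring(s, p, p)
  }
  out
}

## ---- site tables -----------------------------------------------------------

site_table_cols <- c("contig", "position", "edit_type", "strand",
                     "edit_count", "total_reads", "edit_ratio",
                     "snp_filtered", "region_class", "in_alu")

empty_sites <- function() {
  data.table(contig = character(), position = integer(),
             edit_type = character(), strand = character(),
             edit_count = integer(), total_reads = integer(),
             edit_ratio = numeric(), snp_filtered = logical(),
             region_class = character(), in_alu = logical())
}

#' Validate an edit-site table
#'
#' Enforces the site invariants: `edit_count <= total_reads`,
#' `edit_ratio == edit_count / total_reads`, `AG` implies `+` strand and
#' `TC` implies `-`.
#'
#' @param sites A site `data.table`.
#' @return `sites`, invisibly (errors otherwise).
#' @export
validate_sites <- function(sites) {
  stopifnot_cols(sites, c("contig", "position", "edit_type", "strand",
                          "edit_count", "total_reads", "edit_ratio"),
                 "site table")
  if (nrow(sites) == 0L) return(invisible(sites))
  if (any(!sites$edit_type %in% c("AG", "TC")))
    abort_format("invalid edit_type (must be AG or TC)")
  if (any(sites$edit_type == "AG" & sites$strand != "+") ||
      any(sites$edit_type == "TC" & sites$strand != "-"))
    abort_format("strand inconsistent with edit_type (AG => +, TC => -)")
  if (any(sites$total_reads < 1L))
    abort_format("total_reads must be >= 1")
  if (any(sites$edit_count < 0L) || any(sites$edit_count > sites$total_reads))
    abort_format("edit_count must lie in [0, total_reads]")
  if (any(abs(sites$edit_ratio - sites$edit_count / sites$total_reads) >
          1e-9))
    abort_format("edit_ratio does not equal edit_count / total_reads")
  invisible(sites)
}

#' Write an edit-site table to TSV
#'
#' On-disk positions are 1-based (stated on the `#` header line). Columns:
#' contig, position, edit_type, strand, edits, reads, ratio, snp_filtered,
#' region_class, in_alu.
#'
#' @param sites Site `data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  sites <- as.data.table(sites)
  for (col in c("snp_filtered", "region_class", "in_alu"))
    if (!col %in% names(sites))
      sites[, (col) := if (col == "region_class") NA_character_ else NA]
  out <- sites[, .(contig, position, edit_type, strand,
                   edits = edit_count, reads = total_reads,
                   ratio = edit_ratio, snp_filtered, region_class, in_alu)]
  con <- file(path, "w")
  writeLines("# positions are 1-based", con)
  close(con)
  fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read an edit-site table written by [write_site_table()]
#'
#' The ratio column is validated against \[0, 1\] and then recomputed as
#' `edits/reads` so that write/read round-trips are exact.
#'
#' @param path Path to the TSV.
#' @return Site `data.table`.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) abort_format("site table not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE, skip = "contig\tposition",
              na.strings = c("NA", ""))
  stopifnot_cols(dt, c("contig", "position", "edit_type", "strand",
                       "edits", "reads", "ratio"), "site table")
  if (nrow(dt) == 0L) return(empty_sites())
  if (any(dt$ratio < 0 | dt$ratio > 1))
    abort_format("site table '%s': ratio outside [0, 1]", path)
  sites <- data.table(
    contig = as.character(dt$contig), position = as.integer(dt$position),
    edit_type = as.character(dt$edit_type), strand = as.character(dt$strand),
    edit_count = as.integer(dt$edits), total_reads = as.integer(dt$reads),
    edit_ratio = as.integer(dt$edits) / as.integer(dt$reads),
    snp_filtered = if ("snp_filtered" %in% names(dt))
      as.logical(dt$snp_filtered) else NA,
    region_class = if ("region_class" %in% names(dt))
      as.character(dt$region_class) else NA_character_,
    in_alu = if ("in_alu" %in% names(dt)) as.logical(dt$in_alu) else NA)
  validate_sites(sites)
  sites[]
}

## ---- gene models -----------------------------------------------------------

gene_feature_levels <- c("exon", "intron", "utr5", "utr3")

#' Read gene models from a 7-column TSV
#'
#' Columns: `gene_id`, `gene_type` (`protein_coding` or
#' `noncoding_or_RNA`), `feature` (`exon`, `intron`, `utr5`, `utr3`),
#' `contig`, `start`, `end` (1-based inclusive, as in GTF), `strand`.
#'
#' @param path Path to the TSV.
#' @return Gene-model `data.table`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort_format("gene-model file not found: %s", path)
  gm <- fread(path, sep = "\t", header = TRUE)
  stopifnot_cols(gm, c("gene_id", "gene_type", "feature", "contig",
                       "start", "end", "strand"), "gene models")
  if (nrow(gm) && any(!gm$feature %in% gene_feature_levels))
    abort_format("unknown gene feature '%s'",
                 setdiff(gm$feature, gene_feature_levels)[1L])
  if (nrow(gm) && any(!gm$gene_type %in%
                      c("protein_coding", "noncoding_or_RNA")))
    abort_format("unknown gene_type '%s'",
                 setdiff(gm$gene_type,
                         c("protein_coding", "noncoding_or_RNA"))[1L])
  if (nrow(gm) && any(gm$start > gm$end))
    abort_format("gene model with start > end")
  gm[]
}

#' Write gene models to TSV
#' @param genes Gene-model `data.table` (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot_cols(genes, c("gene_id", "gene_type", "feature", "contig",
                          "start", "end", "strand"), "gene models")
  fwrite(as.data.table(genes), path, sep = "\t")
  invisible(path)
}

## ---- cohort ----------------------------------------------------------------

cohort_required_cols <- c("patient_id", "phase", "survival_weeks", "event")
cohort_covariate_cols <- c("adar_expr", "gzma_expr", "prf1_expr",
                           "mutation_load", "neoantigen_load",
                           "neopeptide_load")

#' Read a patient cohort CSV
#'
#' Required columns: `patient_id`, `phase` (`pre`/`on`), `survival_weeks`,
#' `event` (0/1). Optional: `aei`, `adar_expr`, `gzma_expr`, `prf1_expr`,
#' `mutation_load`, `neoantigen_load`, `neopeptide_load`. Missing
#' covariates are kept as `NA`; `cytolytic_score` is derived as the
#' geometric mean of `gzma_expr` and `prf1_expr` where both are present.
#'
#' @param path Path to the CSV.
#' @return Cohort `data.table`, one row per (patient, phase).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort_format("cohort file not found: %s", path)
  co <- fread(path, na.strings = c("NA", ""))
  stopifnot_cols(co, cohort_required_cols, "cohort table")
  if (any(is.na(co$survival_weeks)) || any(co$survival_weeks < 0))
    abort_format("cohort: survival_weeks must be present and >= 0")
  if (any(!co$event %in% c(0L, 1L)))
    abort_format("cohort: event must be 0 or 1")
  if (any(!co$phase %in% c("pre", "on")))
    abort_format("cohort: phase must be 'pre' or 'on'")
  for (col in cohort_covariate_cols)
    if (!col %in% names(co)) co[, (col) := NA_real_]
  co[, cytolytic_score := fifelse(
    !is.na(gzma_expr) & !is.na(prf1_expr) & gzma_expr > 0 & prf1_expr > 0,
    sqrt(gzma_expr * prf1_expr), NA_real_)]
  co[]
}

#' Write a cohort table to CSV
#' @param cohort Cohort `data.table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  fwrite(as.data.table(cohort), path)
  invisible(path)
}
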