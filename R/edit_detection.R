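## Candidate-site calling and the tiered category filters.
##
## Only A>G (called on "+") and T>C (called on "-") mismatches can be
## A-to-I editing in sequencing data: inosine pairs like guanosine, so an
## edited adenosine reads as G on the strand carrying the A and as C on
## its complement. All other mismatch classes never produce sites. Strand
## is assigned purely from the mismatch class; gene-model strand is never
## consulted at detection time.

#' The three editing-site categories
#'
#' Tier definitions: `all` keeps any site with at least 1 edit and 1 read;
#' `standard` requires edit/read ratio >= 0.05 and >= 5 total reads;
#' `stringent` requires ratio >= 0.25 and >= 10 total reads. With
#' `strict = TRUE` every threshold becomes a strict inequality (`>`).
#'
#' @param strict Use strict (`>`) instead of inclusive (`>=`) thresholds.
#' @return Named list of category definitions
#'   (`min_ratio`, `min_reads`, `min_edits`, `strict`).
#' @export
site_categories <- function(strict = FALSE) {
  stopifnot(is_flag(strict))
  list(
    all       = list(name = "all", min_ratio = 0,    min_reads = 1L,
                     min_edits = 1L, strict = strict),
    standard  = list(name = "standard", min_ratio = 0.05, min_reads = 5L,
                     min_edits = 1L, strict = strict),
    stringent = list(name = "stringent", min_ratio = 0.25, min_reads = 10L,
                     min_edits = 1L, strict = strict))
}

resolve_category <- function(category, strict = FALSE) {
  if (is.list(category)) return(category)
  cats <- site_categories(strict)
  if (!is.character(category) || length(category) != 1L ||
      !category %in% names(cats))
    abort_format("unknown site category '%s' (use all/standard/stringent)",
                 paste(category, collapse = ","))
  cats[[category]]
}

#' Call candidate A-to-I editing sites from a pileup
#'
#' Emits a site wherever the reference base is `A` with at least one `G`
#' observed (edit type `AG`, strand `+`) or `T` with at least one `C`
#' (`TC`, strand `-`). `edit_count` is the mismatch-base count and
#' `total_reads` the full column depth (other mismatches at the position
#' count toward depth but never toward edits). Reference-`N` positions are
#' skipped; no other mismatch class produces a site.
#'
#' @param pileup Pileup `data.table` with columns `contig`, `pos`, `ref`,
#'   `A`, `C`, `G`, `T` (e.g. from [read_alignments_or_pileup()]).
#' @param reference Optional `DNAStringSet`; used to fill or cross-check
#'   the `ref` column.
#' @return Site `data.table` ordered by (contig, position).
#' @export
call_candidate_sites <- function(pileup, reference = NULL) {
  pu <- as.data.table(pileup)
  stopifnot_cols(pu, c("contig", "pos", "A", "C", "G", "T"), "pileup")
  if (nrow(pu) == 0L) return(empty_sites())
  cnt <- as.matrix(pu[, c("A", "C", "G", "T")])
  if (any(cnt < 0))
    abort_format("pileup has negative counts")
  if ("depth" %in% names(pu) && any(rowSums(cnt) > pu$depth))
    abort_format("pileup column counts exceed stated depth")
  if (!"ref" %in% names(pu)) {
    if (is.null(reference))
      abort_format("pileup lacks a 'ref' column and no reference was given")
    pu[, ref := reference_base(reference, contig, pos)]
  }
  depth <- rowSums(cnt)
  ag <- pu$ref == "A" & pu$G >= 1L
  tc <- pu$ref == "T" & pu$C >= 1L
  sites <- rbind(
    data.table(contig = pu$contig[ag], position = as.integer(pu$pos[ag]),
               edit_type = "AG", strand = "+",
               edit_count = as.integer(pu$G[ag]),
               total_reads = as.integer(depth[ag])),
    data.table(contig = pu$contig[tc], position = as.integer(pu$pos[tc]),
               edit_type = "TC", strand = "-",
               edit_count = as.integer(pu$C[tc]),
               total_reads = as.integer(depth[tc])))
  if (nrow(sites) == 0L) return(empty_sites())
  sites[, edit_ratio := edit_count / total_reads]
  sites[, `:=`(snp_filtered = NA, region_class = NA_character_,
               in_alu = NA)]
  setorder(sites, contig, position)
  validate_sites(sites)
  sites[]
}

#' Remove sites at known SNP positions
#'
#' A cataloged polymorphism produces the same mismatch signature as
#' editing, so any candidate at a known-SNP coordinate is dropped.
#' Retained sites keep their input order and are flagged
#' `snp_filtered = TRUE` (meaning: the filter has been applied).
#'
#' @param sites Site `data.table`.
#' @param snp_positions `data.table`/`data.frame` with `contig`,
#'   `position` (1-based), e.g. from [read_vcf_positions()].
#' @return `list(sites = retained, removed_count = n)`.
#' @export
filter_known_snps <- function(sites, snp_positions) {
  sites <- as.data.table(sites)
  snp <- as.data.table(snp_positions)
  if (nrow(sites) == 0L)
    return(list(sites = sites, removed_count = 0L))
  if (nrow(snp) == 0L) {
    out <- copy(sites)[, snp_filtered := TRUE]
    return(list(sites = out, removed_count = 0L))
  }
  stopifnot_cols(snp, c("contig", "position"), "SNP positions")
  key <- paste(sites$contig, sites$position)
  hit <- key %in% paste(snp$contig, snp$position)
  out <- copy(sites[!hit])[, snp_filtered := TRUE]
  list(sites = out, removed_count = sum(hit))
}

#' Apply a category filter to a site table
#'
#' Retains sites with `edit_ratio >= min_ratio`, `total_reads >=
#' min_reads` and `edit_count >= min_edits` (all inequalities strict when
#' the category was built with `strict = TRUE`).
#'
#' @param sites Site `data.table`.
#' @param category `"all"`, `"standard"`, `"stringent"`, or a definition
#'   from [site_categories()].
#' @param strict Strict-inequality switch (ignored when `category` is a
#'   definition list, which carries its own).
#' @return The retained subset, input order preserved.
#' @export
apply_category <- function(sites, category = "standard", strict = FALSE) {
  cat <- resolve_category(category, strict)
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L) return(sites)
  if (any(sites$edit_ratio < 0 | sites$edit_ratio > 1))
    abort_format("edit_ratio outside [0, 1]")
  keep <- if (isTRUE(cat$strict)) {
    sites$edit_ratio > cat$min_ratio &
      sites$total_reads > cat$min_reads &
      sites$edit_count > cat$min_edits
  } else {
    sites$edit_ratio >= cat$min_ratio &
      sites$total_reads >= cat$min_reads &
      sites$edit_count >= cat$min_edits
  }
  sites[keep]
}
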