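## Region-class and Alu annotation of editing sites.
##
## Class precedence when a position overlaps several feature classes:
## utr3 > utr5 > exonic_cds > noncoding_or_RNA > intronic > intergenic.
## Any interval belonging to a noncoding_or_RNA gene annotates as
## noncoding_or_RNA regardless of its feature kind; protein-coding exons
## outside an annotated UTR are exonic_cds. Strand is ignored for overlap.
## When two genes could claim a position at the same precedence level, the
## gene that is first by (interval start, gene_id) wins.

region_class_levels <- c("utr3", "utr5", "exonic_cds", "noncoding_or_RNA",
                         "intronic", "intergenic")

#' Build an annotation index from gene models and Alu intervals
#'
#' Precomputes per-class `GRanges` so that point queries run through
#' interval-tree overlap rather than linear scans.
#'
#' @param gene_models Gene-model `data.table` (see [read_gene_models()]);
#'   may be empty.
#' @param alu_intervals Interval `data.table` with `contig`, `start`,
#'   `end` (1-based closed; see [read_bed()]); may be empty.
#' @return An object of class `annotation_index`.
#' @export
build_annotation_index <- function(gene_models = NULL, alu_intervals = NULL) {
  gm <- if (is.null(gene_models)) {
    data.table(gene_id = character(), gene_type = character(),
               feature = character(), contig = character(),
               start = integer(), end = integer(), strand = character())
  } else as.data.table(gene_models)
  alu <- if (is.null(alu_intervals)) {
    data.table(contig = character(), start = integer(), end = integer(),
               label = character())
  } else as.data.table(alu_intervals)

  as_gr <- function(dt) {
    GenomicRanges::GRanges(
      seqnames = dt$contig,
      ranges = IRanges::IRanges(start = dt$start, end = dt$end))
  }
  class_tab <- if (nrow(gm)) {
    nc <- gm$gene_type == "noncoding_or_RNA"
    cls <- character(nrow(gm))
    cls[nc] <- "noncoding_or_RNA"
    cls[!nc & gm$feature == "utr3"] <- "utr3"
    cls[!nc & gm$feature == "utr5"] <- "utr5"
    cls[!nc & gm$feature == "exon"] <- "exonic_cds"
    cls[!nc & gm$feature == "intron"] <- "intronic"
    cbind(gm, data.table(region_class = cls))
  } else {
    cbind(gm, data.table(region_class = character()))
  }
  by_class <- lapply(setNames(nm = setdiff(region_class_levels,
                                           "intergenic")), function(cl) {
    sub <- class_tab[region_class == cl]
    setorder(sub, start, gene_id)
    gr <- as_gr(sub)
    S4Vectors::mcols(gr)$gene_id <- sub$gene_id
    gr
  })
  structure(list(by_class = by_class, alu = as_gr(alu),
                 alu_table = alu, gene_models = gm),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  n_feat <- sum(vapply(x$by_class, length, integer(1L)))
  cat(sprintf("annotation_index: %d gene feature interval(s), %d Alu interval(s)\n",
              n_feat, length(x$alu)))
  invisible(x)
}

#' Annotate sites with region class and Alu membership
#'
#' Assigns each site exactly one `region_class` (precedence documented in
#' [build_annotation_index()]) and `in_alu = TRUE` iff the position
#' overlaps any Alu interval. Counts, depths and ratios are never altered.
#'
#' @param sites Site `data.table`.
#' @param index An `annotation_index`.
#' @return The sites with `region_class` and `in_alu` filled.
#' @export
annotate_sites <- function(sites, index) {
  if (!inherits(index, "annotation_index"))
    abort_format("index must come from build_annotation_index()")
  sites <- copy(as.data.table(sites))
  if (nrow(sites) == 0L) return(sites)
  pts <- GenomicRanges::GRanges(
    seqnames = sites$contig,
    ranges = IRanges::IRanges(start = sites$position, width = 1L))
  cls <- rep("intergenic", nrow(sites))
  unresolved <- rep(TRUE, nrow(sites))
  for (cl in setdiff(region_class_levels, "intergenic")) {
    gr <- index$by_class[[cl]]
    if (length(gr) == 0L) next
    hits <- GenomicRanges::findOverlaps(pts, gr)
    hit_idx <- unique(S4Vectors::queryHits(hits))
    take <- hit_idx[unresolved[hit_idx]]
    cls[take] <- cl
    unresolved[take] <- FALSE
  }
  alu_flag <- rep(FALSE, nrow(sites))
  if (length(index$alu))
    alu_flag[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(pts, index$alu)))] <- TRUE
  sites[, `:=`(region_class = cls, in_alu = alu_flag)]
  sites[]
}

#' Summarize annotated sites per (region class, Alu) cell
#'
#' @param sites Annotated site `data.table` (no `NA` region classes).
#' @return `data.table` with one row per (region_class, in_alu) cell —
#'   all 12 cells always present — carrying `n_sites`, `mean_reads`,
#'   `mean_edits`, `mean_ratio` (`NA` where `n_sites == 0`).
#' @export
summarize_by_region <- function(sites) {
  sites <- as.data.table(sites)
  if (nrow(sites) && (any(is.na(sites$region_class)) ||
                      any(is.na(sites$in_alu))))
    abort_format("sites are not annotated; run annotate_sites() first")
  grid <- CJ(region_class = region_class_levels, in_alu = c(FALSE, TRUE))
  if (nrow(sites) == 0L) {
    grid[, `:=`(n_sites = 0L, mean_reads = NA_real_,
                mean_edits = NA_real_, mean_ratio = NA_real_)]
    return(grid[])
  }
  agg <- sites[, .(n_sites = .N,
                   mean_reads = mean(total_reads),
                   mean_edits = mean(edit_count),
                   mean_ratio = mean(edit_ratio)),
               by = .(region_class, in_alu)]
  out <- agg[grid, on = c("region_class", "in_alu")]
  out[is.na(n_sites), n_sites := 0L]
  out[, region_class := factor(region_class,
                               levels = region_class_levels)]
  setorder(out, region_class, in_alu)
  out[, region_class := as.character(region_class)]
  out[]
}

#' Compare site sets across sample groups
#'
#' Site identity is the key (contig, position, edit_type). Reports how
#' many distinct sites appear in exactly one group versus in several, and
#' keeps the per-group unique keys retrievable.
#'
#' @param profiles_by_group Named list (>= 2 entries) of either site
#'   tables or lists of `sample_profile`s / site tables; each group's site
#'   keys are pooled across its samples.
#' @return `list(unique_counts =, shared_count =, unique_keys =,
#'   shared_keys =)`.
#' @export
site_set_comparison <- function(profiles_by_group) {
  if (!is.list(profiles_by_group) || length(profiles_by_group) < 2L)
    abort_format("site_set_comparison needs at least two groups")
  if (is.null(names(profiles_by_group)) ||
      any(!nzchar(names(profiles_by_group))))
    names(profiles_by_group) <- paste0("group",
                                       seq_along(profiles_by_group))
  keys_of <- function(x) {
    if (inherits(x, "sample_profile")) x <- x$sites
    if (is.data.frame(x))
      return(unique(paste(x$contig, x$position, x$edit_type, sep = ":")))
    unique(unlist(lapply(x, keys_of), use.names = FALSE))
  }
  group_keys <- lapply(profiles_by_group, keys_of)
  all_keys <- unlist(group_keys, use.names = FALSE)
  membership <- table(unique(data.table(
    site_key = all_keys,
    grp = rep(names(group_keys), lengths(group_keys))))$site_key)
  shared_keys <- names(membership)[membership > 1L]
  unique_keys <- lapply(group_keys, function(k)
    k[!(k %in% shared_keys)])
  list(unique_counts = vapply(unique_keys, length, integer(1L)),
       shared_count = length(shared_keys),
       unique_keys = unique_keys,
       shared_keys = shared_keys)
}
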