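## The genome-wide A-to-I editing index (AEI) and the cytolytic score.
##
## AEI = sum of per-site edit/read ratios over the sites that survive a
## category filter; it is additive over disjoint site partitions, grows
## when sites are added and shrinks when the category tightens. The
## headline index uses the standard tier (ratio >= 0.05, reads >= 5);
## all three tiers are always computed on a profile.

#' Compute the A-to-I editing index
#'
#' @param sites Site `data.table` (SNP-filtered).
#' @param category Category name or definition (see [site_categories()]).
#' @param strict Strict-inequality switch for the thresholds.
#' @return Sum of `edit_ratio` over sites surviving the filter; 0 when no
#'   site survives.
#' @export
compute_aei <- function(sites, category = "standard", strict = FALSE) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0L) return(0)
  if (any(!is.finite(sites$edit_ratio)) ||
      any(sites$edit_ratio < 0 | sites$edit_ratio > 1))
    abort_format("edit_ratio outside [0, 1]")
  sum(apply_category(sites, category, strict)$edit_ratio)
}

#' Profile one sample: detect, SNP-filter, and index
#'
#' Runs the full per-sample chain — candidate calling, known-SNP removal,
#' and the AEI under every category tier — and records the per-stage site
#' counts.
#'
#' @param pileup Pileup `data.table`.
#' @param reference Optional `DNAStringSet` (needed if the pileup lacks a
#'   `ref` column).
#' @param snps SNP positions (`contig`, `position`), or `NULL`.
#' @param category Headline category tier (default `"standard"`).
#' @param sample_id,phase Identification carried on the profile.
#' @param strict Strict-inequality switch.
#' @return A `sample_profile`: list with `sample_id`, `phase`, `sites`
#'   (SNP-filtered, all tiers), `aei` (headline), `aei_by_category`,
#'   `category`, `stage_counts`.
#' @export
profile_sample <- function(pileup, reference = NULL, snps = NULL,
                           category = "standard", sample_id = "sample",
                           phase = NA_character_, strict = FALSE) {
  called <- call_candidate_sites(pileup, reference)
  flt <- filter_known_snps(called,
                           snps %||% data.table(contig = character(),
                                                position = integer()))
  sites <- flt$sites
  cats <- site_categories(strict)
  aei_by_category <- vapply(cats, function(ct) compute_aei(sites, ct),
                            numeric(1L))
  n_by_category <- vapply(cats, function(ct) nrow(apply_category(sites, ct)),
                          integer(1L))
  structure(list(
    sample_id = sample_id,
    phase = phase,
    sites = sites,
    category = resolve_category(category, strict)$name,
    aei = unname(aei_by_category[resolve_category(category, strict)$name]),
    aei_by_category = aei_by_category,
    stage_counts = c(called = nrow(called),
                     snp_removed = flt$removed_count,
                     retained = nrow(sites),
                     n_by_category)),
    class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("sample_profile '%s' (phase %s)\n", x$sample_id, x$phase))
  cat(sprintf("  sites called %d, SNP-removed %d, retained %d\n",
              x$stage_counts[["called"]], x$stage_counts[["snp_removed"]],
              x$stage_counts[["retained"]]))
  cat(sprintf("  AEI: all %.3f | standard %.3f | stringent %.3f\n",
              x$aei_by_category[["all"]], x$aei_by_category[["standard"]],
              x$aei_by_category[["stringent"]]))
  invisible(x)
}

#' Cytolytic score
#'
#' Geometric mean of GZMA and PRF1 expression, a proxy for intratumoral
#' cytotoxic activity. Vectorized; both inputs must be strictly positive.
#'
#' @param gzma_expr,prf1_expr Positive expression levels.
#' @return `sqrt(gzma_expr * prf1_expr)`.
#' @export
cytolytic_score <- function(gzma_expr, prf1_expr) {
  if (length(gzma_expr) != length(prf1_expr))
    abort_format("gzma_expr and prf1_expr must have equal length")
  if (any(!is.finite(gzma_expr)) || any(!is.finite(prf1_expr)) ||
      any(gzma_expr <= 0) || any(prf1_expr <= 0))
    abort_format("cytolytic_score requires strictly positive expression")
  sqrt(gzma_expr * prf1_expr)
}
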