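# Analysis loci: 1 Mb windows around index SNPs, merged when adjacent
# index SNPs are close or in LD, minus the MHC.

#' Define primary loci around index SNPs
#'
#' Each index SNP anchors a window of `window` bp centered on its position
#' (`pos +/- window/2`), clipped at 1. The index SNP is the variant with
#' the smallest marginal p-value of its locus.
#'
#' @param index_snps Tibble of index-SNP summary statistics (rows of a
#'   [read_sumstats()] tibble).
#' @param window Window size in bp (default 1 Mb).
#' @return Tibble of loci: `locus_id, chrom, start, end, index_rsid,
#'   index_pos, index_pvalue, merged_from` (list-column of constituent
#'   index rsids).
#' @export
define_loci <- function(index_snps, window = 1e6) {
  x <- index_snps %>% arrange(.data$chrom, .data$pos)
  if (anyDuplicated(x[, c("chrom", "pos")])) {
    abort("duplicate index SNP positions")
  }
  tibble(
    locus_id = paste0("locus_", x$rsid),
    chrom = x$chrom,
    start = pmax(1, x$pos - window / 2),
    end = x$pos + window / 2,
    index_rsid = x$rsid,
    index_pos = x$pos,
    index_pvalue = x$pvalue,
    merged_from = as.list(x$rsid)
  )
}

#' Merge overlapping or correlated loci
#'
#' Adjacent loci on a chromosome whose index SNPs are less than
#' `dist_threshold` bp apart, or whose index SNPs have pairwise `r^2`
#' above `r2_threshold` in the panel, are merged transitively. A merged
#' locus spans the union of the constituent bounds and takes the
#' constituent index SNP with the smallest p-value as its index. Merging
#' is iterated to a fixed point, so a second call changes nothing.
#'
#' @param loci Tibble from [define_loci()].
#' @param panel Optional [genotype_panel()] supplying index-SNP LD; when
#'   `NULL` (or when an index SNP is absent from the panel) only the
#'   distance criterion applies.
#' @param dist_threshold Merge distance between index SNPs, bp.
#' @param r2_threshold Merge LD threshold (`r^2` strictly greater).
#' @return Tibble of merged loci.
#' @export
merge_loci <- function(loci, panel = NULL, dist_threshold = 1e6,
                       r2_threshold = 0.1) {
  repeat {
    merged <- merge_loci_once(loci, panel, dist_threshold, r2_threshold)
    if (nrow(merged) == nrow(loci)) return(merged)
    loci <- merged
  }
}

merge_loci_once <- function(loci, panel, dist_threshold, r2_threshold) {
  loci %>%
    arrange(.data$chrom, .data$index_pos) %>%
    group_by(.data$chrom) %>%
    mutate(.grp = cumsum(!merge_with_prev(.data$index_rsid, .data$index_pos,
                                          panel, dist_threshold,
                                          r2_threshold))) %>%
    group_by(.data$chrom, .data$.grp) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      .best = which.min(.data$index_pvalue),
      index_rsid = .data$index_rsid[.data$.best],
      index_pos = .data$index_pos[.data$.best],
      index_pvalue = .data$index_pvalue[.data$.best],
      merged_from = list(unlist(.data$merged_from)),
      .groups = "drop"
    ) %>%
    mutate(locus_id = paste0("locus_", .data$index_rsid)) %>%
    select("locus_id", "chrom", "start", "end",
           "index_rsid", "index_pos", "index_pvalue",
           "merged_from")
}

# For loci ordered by position within one chromosome: does locus i merge
# with locus i-1? First element is FALSE (starts a new group).
merge_with_prev <- function(rsid, pos, panel, dist_threshold, r2_threshold) {
  k <- length(rsid)
  if (k <= 1) return(rep(FALSE, k))
  near <- c(FALSE, diff(pos) < dist_threshold)
  if (!is.null(panel)) {
    in_panel <- rsid %in% panel$variants$rsid
    for (i in which(!near[-1]) + 1) {
      if (in_panel[i] && in_panel[i - 1]) {
        r <- ld_with(panel, rsid[i], rsid[i - 1])
        near[i] <- r^2 > r2_threshold
      }
    }
  }
  near
}

#' Remove loci overlapping a region
#'
#' Drops loci overlapping the given interval; by default the extended MHC
#' (chr6:25-34 Mb, b37), which is excluded from the search for independent
#' signals because of its LD complexity.
#'
#' @param loci Tibble from [define_loci()] or [merge_loci()].
#' @param chrom,start,end Region to exclude (1-based, inclusive).
#' @return Loci tibble without the overlapping loci; removals are reported.
#' @export
exclude_region <- function(loci, chrom = "6", start = 25e6, end = 34e6) {
  hit <- loci$chrom == as.character(chrom) &
    loci$start <= end & loci$end >= start
  if (any(hit)) {
    inform(sprintf("exclude_region: removed %d locus/loci overlapping %s:%s-%s (%s)",
                   sum(hit), chrom, format(start, scientific = FALSE),
                   format(end, scientific = FALSE),
                   paste(loci$locus_id[hit], collapse = ", ")))
  }
  loci[!hit, , drop = FALSE]
}

#' Enumerate candidate SNPs of a locus
#'
#' All harmonized summary-statistics variants inside the locus bounds that
#' are present in the panel, excluding the index SNP and any already
#' confirmed signals.
#'
#' @param sumstats Harmonized sumstats tibble ([harmonize_sumstats()]).
#' @param locus One row of a loci tibble.
#' @param panel A [genotype_panel()].
#' @param exclude Additional rsids to exclude (confirmed signals).
#' @return Tibble of candidate variant records.
#' @export
enumerate_candidates <- function(sumstats, locus, panel, exclude = character()) {
  out <- sumstats %>%
    filter(.data$chrom == locus$chrom,
           .data$pos >= locus$start, .data$pos <= locus$end,
           .data$rsid %in% colnames(panel$dosages),
           !.data$rsid %in% c(locus$index_rsid, exclude))
  if (nrow(out) == 0) {
    warn(sprintf("locus %s has no candidate SNPs; inactive", locus$locus_id))
  }
  out
}
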