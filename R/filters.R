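#' Drop low-frequency tags within each gene
#'
#' Within every gene, tags are ranked by aggregate count (summed over all
#' libraries) from highest to lowest and retained from the top until the
#' retained tags represent more than `coverage` of the gene's aggregate
#' frequency; the remaining minor tags are discarded. Ties in aggregate count
#' are broken proximal-first, then by tag id. A gene whose aggregate count is
#' zero is left untouched (there is no frequency evidence to rank on), and if
#' the cumulative share never strictly exceeds `coverage` (e.g. `coverage =
#' 1`) all tags are kept.
#'
#' @param t a [tag_count_table()].
#' @param coverage fraction in (0, 1]; default 0.9.
#' @return The filtered [tag_count_table()].
#' @export
filter_minor_tags <- function(t, coverage = 0.9) {
  stopifnot(inherits(t, "TagCountTable"))
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage > 1)
    stop("coverage must be a fraction in (0, 1]")
  agg <- rowSums(t$counts)
  keep <- logical(nrow(t$tags))
  idx_by_gene <- split(seq_len(nrow(t$tags)),
                       factor(t$tags$gene_id, levels = unique(t$tags$gene_id)))
  for (idx in idx_by_gene) {
    tot <- sum(agg[idx])
    if (tot <= 0) {
      keep[idx] <- TRUE
      next
    }
    # idx is already proximal->distal, so seq_along(idx) is the proximal rank
    o <- idx[order(-agg[idx], seq_along(idx), t$tags$tag_id[idx])]
    share <- cumsum(agg[o]) / tot
    cut <- which(share > coverage)
    n_keep <- if (length(cut) == 0L) length(o) else cut[1L]
    keep[o[seq_len(n_keep)]] <- TRUE
  }
  .subset_tags(t, keep)
}

#' Drop genes represented by a single tag
#'
#' Association within a gene needs at least two alternative poly(A)-site tags
#' (Z_g >= 2); genes with a single tag carry no within-gene usage signal.
#'
#' @param t a [tag_count_table()].
#' @return The filtered [tag_count_table()].
#' @export
filter_single_tag_genes <- function(t) {
  stopifnot(inherits(t, "TagCountTable"))
  z <- gene_sizes(t)
  keep <- t$tags$gene_id %in% names(z)[z >= 2L]
  if (!any(keep))
    stop("no multi-tag genes remain after filtering")
  .subset_tags(t, keep)
}

.subset_tags <- function(t, keep) {
  out <- t
  out$tags <- t$tags[keep, , drop = FALSE]
  rownames(out$tags) <- NULL
  out$counts <- t$counts[keep, , drop = FALSE]
  out
}
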