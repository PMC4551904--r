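#' Condition-ratio difference of a tag
#'
#' For one tag, the difference between its stimulated-state and rest-state
#' usage ratios, where each ratio is the tag's count summed over the
#' replicates of one condition divided by its count summed over all
#' replicates of both conditions. Values lie in \[-1, 1\]: +1 means all
#' counts in stimulation, -1 all counts at rest, 0 perfectly balanced. A tag
#' with zero total count has no defined ratio and returns `NA` (the
#' unclassified marker).
#'
#' @param t a [tag_count_table()].
#' @param tag_id the tag.
#' @return Numeric in \[-1, 1\], or `NA`.
#' @export
condition_ratio_diff <- function(t, tag_id) {
  stopifnot(inherits(t, "TagCountTable"))
  row <- match(tag_id, t$tags$tag_id)
  if (is.na(row)) stop("unknown tag_id: ", tag_id)
  li <- .lib_index(t)
  rest_sum <- sum(t$counts[row, li$cond1])
  stim_sum <- sum(t$counts[row, li$cond2])
  tot <- rest_sum + stim_sum
  if (tot == 0) return(NA_real_)
  stim_sum / tot - rest_sum / tot
}

# sign rule shared by the two- and three-tag classifiers
.classify_pair <- function(dx, dy) {
  if (is.na(dx) || is.na(dy) || dx == 0 || dy == 0) return("unclassified")
  if (dx > 0 && dy > 0) return("positive_accordance")
  if (dx < 0 && dy < 0) return("negative_accordance")
  if (dx < 0 && dy > 0) return("forward_switch")
  "backward_switch"
}

#' Classify the transcription pattern of a two-tag gene
#'
#' With `x` the condition-ratio difference of the proximal tag and `y` that
#' of the distal tag, the four sign quadrants define the patterns: both
#' positive = positive accordance (both isoforms rise under stimulation),
#' both negative = negative accordance, proximal down / distal up = forward
#' switch (usage moves proximal to distal), proximal up / distal down =
#' backward switch. A zero or undefined difference leaves the pair
#' unclassified.
#'
#' @param t a [tag_count_table()].
#' @param gene_id the gene.
#' @param declared_tags character vector of declared tag ids; the gene must
#'   contribute exactly two of them.
#' @return A one-row data.frame (class `PatternCall`) with columns `gene_id`,
#'   `pair`, `proximal_tag`, `distal_tag`, `dx`, `dy`, `pattern`.
#' @export
classify_two_tag <- function(t, gene_id, declared_tags) {
  stopifnot(inherits(t, "TagCountTable"))
  idx <- which(t$tags$gene_id == gene_id &
                 t$tags$tag_id %in% declared_tags)
  if (length(idx) != 2L)
    stop("gene '", gene_id, "' must have exactly two declared tags (found ",
         length(idx), ")")
  # table rows are already ordered proximal -> distal within the gene
  prox <- t$tags$tag_id[idx[1L]]
  dist <- t$tags$tag_id[idx[2L]]
  dx <- condition_ratio_diff(t, prox)
  dy <- condition_ratio_diff(t, dist)
  structure(
    data.frame(gene_id = gene_id, pair = "proximal-distal",
               proximal_tag = prox, distal_tag = dist,
               dx = dx, dy = dy, pattern = .classify_pair(dx, dy),
               stringsAsFactors = FALSE),
    class = c("PatternCall", "data.frame"))
}

#' Classify the transcription patterns of a three-tag gene
#'
#' Applies the two-tag sign rule to each ordered pair of the gene's three
#' declared tags: proximal-middle, proximal-distal and middle-distal.
#'
#' @inheritParams classify_two_tag
#' @return A three-row data.frame (class `PatternCall`), one row per pair.
#' @export
classify_three_tag <- function(t, gene_id, declared_tags) {
  stopifnot(inherits(t, "TagCountTable"))
  idx <- which(t$tags$gene_id == gene_id &
                 t$tags$tag_id %in% declared_tags)
  if (length(idx) != 3L)
    stop("gene '", gene_id, "' must have exactly three declared tags (found ",
         length(idx), ")")
  ids <- t$tags$tag_id[idx]            # proximal, middle, distal
  d <- vapply(ids, function(id) condition_ratio_diff(t, id), numeric(1L))
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  lab <- c("proximal-middle", "proximal-distal", "middle-distal")
  out <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    i <- pairs[[k]][1L]; j <- pairs[[k]][2L]
    data.frame(gene_id = gene_id, pair = lab[k],
               proximal_tag = ids[i], distal_tag = ids[j],
               dx = d[i], dy = d[j],
               pattern = .classify_pair(d[i], d[j]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("PatternCall", "data.frame"))
}

#' Classify all genes with two or three declared tags
#'
#' Driver over a declared tag set: every gene contributing exactly two
#' declared tags gets a two-tag call, every gene contributing exactly three
#' gets the three pairwise calls; other genes are skipped.
#'
#' @param t a [tag_count_table()].
#' @param declared character vector of declared tag ids.
#' @return data.frame of pattern calls (possibly zero rows).
#' @export
classify_declared <- function(t, declared) {
  stopifnot(inherits(t, "TagCountTable"))
  sub <- t$tags[t$tags$tag_id %in% declared, , drop = FALSE]
  n_by_gene <- table(sub$gene_id)
  calls <- list()
  for (g in names(n_by_gene)) {
    if (n_by_gene[[g]] == 2L)
      calls[[g]] <- classify_two_tag(t, g, declared)
    else if (n_by_gene[[g]] == 3L)
      calls[[g]] <- classify_three_tag(t, g, declared)
  }
  if (length(calls) == 0L)
    return(data.frame(gene_id = character(0), pair = character(0),
                      proximal_tag = character(0), distal_tag = character(0),
                      dx = numeric(0), dy = numeric(0),
                      pattern = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Symmetric fold change of a tag between conditions
#'
#' The larger of the two directional ratios of replicate-mean counts
#' (stimulated over rest, rest over stimulated), so values are always >= 1.
#' If exactly one condition mean is zero the fold change is `Inf` (an
#' all-or-nothing change); if both are zero it is 1 (no evidence of change).
#' A screen of the form "fold change > 1.4 or < 1/1.4" is the symmetric
#' condition `fold_change(t, id) > 1.4`.
#'
#' @param t a [tag_count_table()].
#' @param tag_id the tag.
#' @return Numeric >= 1, possibly `Inf`.
#' @export
fold_change <- function(t, tag_id) {
  stopifnot(inherits(t, "TagCountTable"))
  row <- match(tag_id, t$tags$tag_id)
  if (is.na(row)) stop("unknown tag_id: ", tag_id)
  li <- .lib_index(t)
  m1 <- mean(t$counts[row, li$cond1])
  m2 <- mean(t$counts[row, li$cond2])
  if (m1 == 0 && m2 == 0) return(1)
  if (m1 == 0 || m2 == 0) return(Inf)
  max(m2 / m1, m1 / m2)
}
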