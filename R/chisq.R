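#' Pearson chi-square of a 2x2 table
#'
#' Computed in closed form as `N * (n11*n22 - n12*n21)^2 / (R1*R2*C1*C2)`
#' where `N` is the grand total and `R`/`C` are row/column totals. Entries may
#' be non-integer (normalized counts or replicate means). A table with any
#' zero marginal carries no association evidence and returns 0 rather than
#' NaN.
#'
#' @param table 2x2 numeric matrix with non-negative entries.
#' @return The chi-square statistic (>= 0).
#' @export
pearson_chi2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop("a 2x2 table is required")
  if (anyNA(tb) || any(tb < 0)) stop("table entries must be non-negative")
  .chi2_cells(tb[1L, 1L], tb[1L, 2L], tb[2L, 1L], tb[2L, 2L])
}

# vectorized closed form; zero marginal -> 0
.chi2_cells <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  r2 <- n21 + n22
  c1 <- n11 + n21
  c2 <- n12 + n22
  n <- r1 + r2
  den <- r1 * r2 * c1 * c2
  num <- n * (n11 * n22 - n12 * n21)^2
  out <- numeric(length(den))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Replicate series of 2x2 tables for one tag
#'
#' For tag `s` in a gene with `Z_g >= 2` tags, builds the `r` replicate 2x2
#' tables with rows = tag states (row 1: tag `s`; row 2: the sum of all other
#' tags of the gene) and columns = conditions (1 = rest, 2 = stimulated).
#'
#' @param t a [tag_count_table()].
#' @param tag_id the tag to extract.
#' @return An object of class `TwoByTwoSeries`: list with `tag_id`, `gene_id`,
#'   `r`, `cells` (a `2 x 2 x r` array indexed `[tag state, condition,
#'   replicate]`) and `n_s` (total count over all cells).
#' @export
build_two_by_two <- function(t, tag_id) {
  stopifnot(inherits(t, "TagCountTable"))
  row <- match(tag_id, t$tags$tag_id)
  if (is.na(row)) stop("unknown tag_id: ", tag_id)
  gene <- t$tags$gene_id[row]
  in_gene <- which(t$tags$gene_id == gene)
  if (length(in_gene) < 2L)
    stop("tag '", tag_id, "' belongs to a single-tag gene; ",
         "within-gene association is undefined")
  li <- .lib_index(t)
  r <- li$r
  own <- t$counts[row, c(li$cond1, li$cond2)]
  rest <- colSums(t$counts[setdiff(in_gene, row), c(li$cond1, li$cond2),
                           drop = FALSE])
  cells <- array(0, dim = c(2L, 2L, r))
  for (v in seq_len(r)) {
    cells[1L, 1L, v] <- own[v]
    cells[1L, 2L, v] <- own[r + v]
    cells[2L, 1L, v] <- rest[v]
    cells[2L, 2L, v] <- rest[r + v]
  }
  structure(list(tag_id = tag_id, gene_id = gene, r = r, cells = cells,
                 n_s = sum(cells)),
            class = "TwoByTwoSeries")
}

#' Treatment chi-square of a tag
#'
#' The Pearson chi-square of the 2x2 table of replicate-mean counts: cell
#' `(i, j)` is the mean over the `r` replicates of condition `j`. It measures
#' association between tag state (tag vs rest-of-gene) and condition, but is
#' biased upward by mean replicate noise, which is why it is compared to an
#' empirical null profile ([null_chi2()]) rather than to the chi-square
#' distribution.
#'
#' @param s a [build_two_by_two()] series.
#' @return The chi-square of the mean table (>= 0).
#' @export
treatment_chi2 <- function(s) {
  stopifnot(inherits(s, "TwoByTwoSeries"))
  m <- apply(s$cells, c(1L, 2L), mean)
  pearson_chi2(m)
}

#' Empirical null chi-square of a tag
#'
#' In analogy to estimating a null variance from within-group variation, the
#' null chi-square is estimated from within-condition replicate variation: a
#' 2x2 table is formed with rows = tag states and columns = two replicates
#' `(u, v)` of the same condition, whose Pearson chi-square measures
#' tag-proportion noise with no condition effect in it. Because a pair table
#' carries single-replicate noise while the treatment statistic
#' ([treatment_chi2()]) is built from `r`-replicate means, the null
#' chi-square overstates the noise of the treatment statistic by a factor of
#' about `r` under no association; the ranked comparison inherits this as a
#' deliberate conservative margin - a tag must beat a noise bar measured at
#' single-replicate scale before it can be declared (on real data most
#' treatment chi-squares fall inside the null profile for exactly this
#' reason).
#'
#' Two aggregation schemes are provided. `"single"` (the default) scores one
#' replicate-pair table, so the per-tag null value keeps the 1-df chi-square
#' shape of a single noise draw; across tags the null profile then has at
#' least the tail weight of the treatment profile's noise component, and the
#' false-positive accounting of [scan_thresholds()] stays conservative.
#' `"mean"` averages the pair chi-squares over all `r*(r-1)/2` unordered
#' pairs and both conditions; it uses all replicate information and has the
#' same expectation, but averaging lightens the profile's upper tail, which
#' can hide extreme treatment-noise draws from the false-positive accounting
#' (see the methods vignette for the trade-off). Under no replicate
#' variation both schemes give exactly 0.
#'
#' @param s a [build_two_by_two()] series with `r >= 2`.
#' @param scheme `"single"` or `"mean"` (see above).
#' @param condition condition (1 or 2) of the pair table for
#'   `scheme = "single"`.
#' @param pair integer pair of distinct replicate indices for
#'   `scheme = "single"`; default `c(1, 2)`. [chi_square_profile()] rotates
#'   `condition` and `pair` deterministically across tags so all replicates
#'   contribute to the null profile.
#' @return The null chi-square (>= 0).
#' @export
null_chi2 <- function(s, scheme = c("single", "mean"),
                      condition = 1L, pair = c(1L, 2L)) {
  stopifnot(inherits(s, "TwoByTwoSeries"))
  scheme <- match.arg(scheme)
  if (s$r < 2L) stop("replicates required for null estimation (r >= 2)")
  if (scheme == "single") {
    stopifnot(condition %in% 1:2, length(pair) == 2L,
              all(pair %in% seq_len(s$r)), pair[1L] != pair[2L])
    tb <- cbind(s$cells[, condition, pair[1L]], s$cells[, condition, pair[2L]])
    return(pearson_chi2(tb))
  }
  vals <- numeric(0)
  for (j in 1:2) {
    for (u in seq_len(s$r - 1L)) {
      for (v in seq.int(u + 1L, s$r)) {
        tb <- cbind(s$cells[, j, u], s$cells[, j, v])
        vals <- c(vals, pearson_chi2(tb))
      }
    }
  }
  mean(vals)
}

# Internal: counts split into tag/rest arrays of shape [S, 2 conditions, r].
.tag_rest_arrays <- function(t) {
  li <- .lib_index(t)
  r <- li$r
  cnt <- t$counts
  gene <- factor(t$tags$gene_id, levels = unique(t$tags$gene_id))
  gene_tot <- rowsum(cnt, gene, reorder = FALSE)
  rest <- gene_tot[as.integer(gene), , drop = FALSE] - cnt
  a1 <- array(0, dim = c(nrow(cnt), 2L, r))
  a2 <- array(0, dim = c(nrow(cnt), 2L, r))
  for (v in seq_len(r)) {
    a1[, 1L, v] <- cnt[, li$cond1[v]]
    a1[, 2L, v] <- cnt[, li$cond2[v]]
    a2[, 1L, v] <- rest[, li$cond1[v]]
    a2[, 2L, v] <- rest[, li$cond2[v]]
  }
  list(tag = a1, rest = a2, r = r)
}

#' Treatment and null chi-squares for every tag of a table
#'
#' Vectorized equivalent of calling [build_two_by_two()], [treatment_chi2()]
#' and [null_chi2()] for each tag. All genes must have `Z_g >= 2` (apply
#' [filter_single_tag_genes()] first). With `null_scheme = "single"` (the
#' default) the condition and replicate pair of each tag's null table are
#' rotated deterministically with the tag's row index, so every condition
#' and pair contributes equally to the null profile while each tag still
#' yields a single-table (distribution-matched) null chi-square.
#'
#' @param t a [tag_count_table()].
#' @param null_scheme passed to the null estimator; see [null_chi2()].
#' @return data.frame with columns `tag_id`, `gene_id`, `chi2_treat`,
#'   `chi2_null`.
#' @export
chi_square_profile <- function(t, null_scheme = c("single", "mean")) {
  stopifnot(inherits(t, "TagCountTable"))
  null_scheme <- match.arg(null_scheme)
  if (any(gene_sizes(t) < 2L))
    stop("single-tag genes present; apply filter_single_tag_genes() first")
  ar <- .tag_rest_arrays(t)
  r <- ar$r
  S <- dim(ar$tag)[1L]
  m1 <- apply(ar$tag, c(1L, 2L), mean)   # S x 2: tag means per condition
  m2 <- apply(ar$rest, c(1L, 2L), mean)
  treat <- .chi2_cells(m1[, 1L], m1[, 2L], m2[, 1L], m2[, 2L])

  pairs <- utils::combn(r, 2L)
  if (null_scheme == "mean") {
    acc <- 0
    for (j in 1:2) {
      for (k in seq_len(ncol(pairs))) {
        u <- pairs[1L, k]; v <- pairs[2L, k]
        acc <- acc + .chi2_cells(ar$tag[, j, u], ar$tag[, j, v],
                                 ar$rest[, j, u], ar$rest[, j, v])
      }
    }
    nullv <- acc / (2L * ncol(pairs))
  } else {
    idx <- seq_len(S) - 1L
    cond <- idx %% 2L + 1L
    pk <- (idx %/% 2L) %% ncol(pairs) + 1L
    nullv <- numeric(S)
    for (j in 1:2) {
      for (k in seq_len(ncol(pairs))) {
        sel <- cond == j & pk == k
        if (!any(sel)) next
        u <- pairs[1L, k]; v <- pairs[2L, k]
        nullv[sel] <- .chi2_cells(ar$tag[sel, j, u], ar$tag[sel, j, v],
                                  ar$rest[sel, j, u], ar$rest[sel, j, v])
      }
    }
  }
  data.frame(tag_id = t$tags$tag_id, gene_id = t$tags$gene_id,
             chi2_treat = treat, chi2_null = nullv,
             stringsAsFactors = FALSE)
}
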