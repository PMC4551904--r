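#' Single-test p-values from the replicate-mean 2x2 table
#'
#' The classical single-table alternatives the ranked chi-square method is
#' compared against: collapse the replicate series to the 2x2 table of
#' replicate means, then test association with the Pearson chi-square (upper
#' tail of the 1-df chi-square distribution, no continuity correction) or the
#' two-sided Fisher exact test. Fisher requires integer counts, so the mean
#' table is rounded (or floored) first; both choices are exposed because the
#' means of normalized counts are generally fractional.
#'
#' @param s a [build_two_by_two()] series.
#' @param method `"pearson"` or `"fisher"`.
#' @param rounding integer coercion for Fisher: `"round"` (default) or
#'   `"floor"`.
#' @return A p-value in \[0, 1\].
#' @export
mean_table_pvalues <- function(s, method = c("pearson", "fisher"),
                               rounding = c("round", "floor")) {
  stopifnot(inherits(s, "TwoByTwoSeries"))
  method <- match.arg(method)
  rounding <- match.arg(rounding)
  m <- apply(s$cells, c(1L, 2L), mean)
  if (sum(m) == 0) {
    warning("zero grand total; returning p = 1")
    return(1)
  }
  if (method == "pearson") {
    stat <- pearson_chi2(m)
    stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  } else {
    tb <- if (rounding == "round") round(m) else floor(m)
    if (sum(tb) == 0) {
      warning("zero grand total after rounding; returning p = 1")
      return(1)
    }
    min(1, stats::fisher.test(tb)$p.value)  # guard the occasional 1 + eps
  }
}

#' Cochran-Mantel-Haenszel test across replicate strata
#'
#' Pools association evidence over replicates: stratum `v` is the 2x2 table
#' of tag state by condition built from replicate `v` of each condition. The
#' statistic is the classical CMH chi-square without continuity correction,
#' `(sum_v (n11v - E11v))^2 / sum_v Var11v`, with hypergeometric moments
#' `E11 = R1*C1/N` and `Var11 = R1*R2*C1*C2 / (N^2 (N - 1))`, referred to the
#' 1-df chi-square upper tail. Degenerate strata (grand total <= 1 or a zero
#' marginal) contribute nothing; if all strata are degenerate the p-value is
#' 1 with a warning.
#'
#' @param s a [build_two_by_two()] series.
#' @return A p-value in \[0, 1\].
#' @export
cmh_pvalue <- function(s) {
  stopifnot(inherits(s, "TwoByTwoSeries"))
  num <- 0
  den <- 0
  informative <- FALSE
  for (v in seq_len(s$r)) {
    tb <- s$cells[, , v]
    n <- sum(tb)
    r1 <- sum(tb[1L, ]); r2 <- sum(tb[2L, ])
    c1 <- sum(tb[, 1L]); c2 <- sum(tb[, 2L])
    if (n <= 1 || r1 * r2 * c1 * c2 == 0) next
    informative <- TRUE
    num <- num + (tb[1L, 1L] - r1 * c1 / n)
    den <- den + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  if (!informative || den == 0) {
    warning("all strata degenerate; returning p = 1")
    return(1)
  }
  stats::pchisq(num^2 / den, df = 1L, lower.tail = FALSE)
}

# vectorized CMH statistic over all tags of a table (degenerate strata skipped)
.cmh_profile <- function(t) {
  ar <- .tag_rest_arrays(t)
  num <- den <- numeric(dim(ar$tag)[1L])
  for (v in seq_len(ar$r)) {
    n11 <- ar$tag[, 1L, v]; n12 <- ar$tag[, 2L, v]
    n21 <- ar$rest[, 1L, v]; n22 <- ar$rest[, 2L, v]
    r1 <- n11 + n12; r2 <- n21 + n22
    c1 <- n11 + n21; c2 <- n12 + n22
    n <- r1 + r2
    ok <- n > 1 & (r1 * r2 * c1 * c2) > 0
    num[ok] <- num[ok] + (n11[ok] - r1[ok] * c1[ok] / n[ok])
    den[ok] <- den[ok] + (r1 * r2 * c1 * c2)[ok] / (n[ok]^2 * (n[ok] - 1))
  }
  stat <- ifelse(den > 0, num^2 / den, 0)
  ifelse(den > 0, stats::pchisq(stat, df = 1L, lower.tail = FALSE), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, forms `p_(i) * m / i`, takes the running
#' minimum from the largest rank down (step-up), caps at 1 and maps back to
#' the input order. Output values never fall below the raw p-values and
#' preserve their ordering.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q[order(o)]
}

#' Baseline p-value profile for a whole table
#'
#' Runs the requested single-test baselines on every tag and adds
#' Benjamini-Hochberg adjusted values per method. Pearson and CMH are
#' vectorized; Fisher loops over tags (each call enumerates exact tables) and
#' is intended for modest table sizes.
#'
#' @param t a [tag_count_table()] with all genes multi-tag.
#' @param methods subset of `c("pearson", "fisher", "cmh")`.
#' @param rounding passed to [mean_table_pvalues()] for Fisher.
#' @return Long-format data.frame with columns `tag_id`, `method`, `p`,
#'   `bh_q`.
#' @export
baseline_pvalues <- function(t, methods = c("pearson", "fisher", "cmh"),
                             rounding = "round") {
  stopifnot(inherits(t, "TagCountTable"))
  bad <- setdiff(methods, c("pearson", "fisher", "cmh"))
  if (length(bad) > 0L)
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; valid methods are pearson, fisher, cmh")
  if (any(gene_sizes(t) < 2L))
    stop("single-tag genes present; apply filter_single_tag_genes() first")
  ar <- .tag_rest_arrays(t)
  res <- list()
  for (method in methods) {
    p <- switch(method,
      pearson = {
        m1 <- apply(ar$tag, c(1L, 2L), mean)
        m2 <- apply(ar$rest, c(1L, 2L), mean)
        stat <- .chi2_cells(m1[, 1L], m1[, 2L], m2[, 1L], m2[, 2L])
        gt <- m1[, 1L] + m1[, 2L] + m2[, 1L] + m2[, 2L]
        ifelse(gt > 0,
               stats::pchisq(stat, df = 1L, lower.tail = FALSE), 1)
      },
      cmh = .cmh_profile(t),
      fisher = vapply(t$tags$tag_id, function(id) {
        suppressWarnings(
          mean_table_pvalues(build_two_by_two(t, id), "fisher",
                             rounding = rounding))
      }, numeric(1L))
    )
    res[[method]] <- data.frame(tag_id = t$tags$tag_id, method = method,
                                p = unname(p), bh_q = bh_adjust(unname(p)),
                                stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
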