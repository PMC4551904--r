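#' Rank the treatment and null chi-square profiles
#'
#' Sorts the per-tag treatment chi-squares and the per-tag null chi-squares
#' ascending, independently of each other, so that the two profiles can be
#' compared position by position. Ties are broken by tag id for determinism.
#'
#' @param pairs data.frame with columns `tag_id`, `chi2_treat`, `chi2_null`
#'   (as returned by [chi_square_profile()]).
#' @return An object of class `RankedProfiles`: list with `sorted_treat`,
#'   `sorted_null` (nondecreasing numeric vectors of common length `S`),
#'   `treat_tags`, `null_tags` (tag ids in sorted order, the back-maps),
#'   `S` and `chi2_null_max`.
#' @export
rank_profiles <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("tag_id", "chi2_treat", "chi2_null") %in% names(pairs)))
  if (nrow(pairs) < 2L) stop("at least two tags are required for ranking")
  if (anyNA(pairs$chi2_treat) || anyNA(pairs$chi2_null) ||
      any(!is.finite(pairs$chi2_treat)) || any(!is.finite(pairs$chi2_null)))
    stop("chi-squares must be finite")
  if (all(pairs$chi2_null <= 0))
    stop("degenerate null distribution: all null chi-squares are zero")
  ot <- order(pairs$chi2_treat, pairs$tag_id)
  oe <- order(pairs$chi2_null, pairs$tag_id)
  structure(
    list(sorted_treat = pairs$chi2_treat[ot],
         sorted_null = pairs$chi2_null[oe],
         treat_tags = pairs$tag_id[ot],
         null_tags = pairs$tag_id[oe],
         S = nrow(pairs),
         chi2_null_max = pairs$chi2_null[oe][nrow(pairs)]),
    class = "RankedProfiles"
  )
}

#' Threshold scan and nonparametric FDR curve
#'
#' Scans thresholds `Delta = U * chi2_null_max` for `U = 0, 1/n_grid, ..., 1`.
#' At each threshold, with `d[k] = sorted_treat[k] - sorted_null[k]`:
#'
#' * `a` is the start of the longest suffix of ranked positions whose `d`
#'   values all exceed `Delta`, so every declared tag satisfies the
#'   declaration rule; if even the top position fails, the record is flagged
#'   with `N = 0` and an undefined (`NA`) FDR.
#' * `N = S - a + 1` tags are declared (the top `N` by treatment chi-square).
#' * `b` is the smallest null rank with `sorted_null[b] - sorted_null[a] >
#'   Delta`; null tags at ranks `b..S` are the potential false positives.
#' * Each potential false positive at null rank `k` is counted with
#'   probability `p(k) = ((sorted_null[k] * k) / (chi2_null_max * S))^x`,
#'   with exponent `x = (2 r / chi2_null_max)^2` by default; `F` is the sum
#'   of these probabilities and `FDR = min(1, F/N)`. If no null rank exceeds
#'   the cut, `F = 0` and `FDR = 0`.
#'
#' Forcing `x = 0` gives `p = 1` for every candidate, the maximally
#' conservative estimate `F = S - b + 1`.
#'
#' @param p a [rank_profiles()] object.
#' @param r number of replicates per condition (enters the exponent `x`).
#' @param n_grid number of grid intervals; the curve has `n_grid + 1` points.
#' @param x optional override of the exponent (e.g. `0`).
#' @return An object of class `FdrCurve`: a data.frame with columns `U`,
#'   `delta`, `a`, `b`, `N`, `F`, `FDR` and attributes `x`, `S`,
#'   `chi2_null_max`.
#' @export
scan_thresholds <- function(p, r, n_grid = 100, x = NULL) {
  stopifnot(inherits(p, "RankedProfiles"))
  n_grid <- as.integer(n_grid)
  if (n_grid < 1L) stop("n_grid must be >= 1")
  S <- p$S
  e <- p$sorted_null
  emax <- p$chi2_null_max
  if (is.null(x)) x <- (2 * r / emax)^2
  d <- p$sorted_treat - e
  # suffix minima: suf[k] = min(d[k..S]); nondecreasing in k
  suf <- rev(cummin(rev(d)))
  # false-positive probability per null rank, and its suffix sums
  base <- (e * seq_len(S)) / (emax * S)
  prob <- base^x
  psuf <- rev(cumsum(rev(prob)))

  U <- seq(0, n_grid) / n_grid
  delta <- U * emax
  a <- b <- rep(NA_integer_, length(U))
  N <- Fd <- numeric(length(U))
  FDR <- rep(NA_real_, length(U))
  for (k in seq_along(U)) {
    n_pass <- sum(suf > delta[k])
    if (n_pass == 0L) next                 # treatment inside null: undefined
    a[k] <- S - n_pass + 1L
    N[k] <- n_pass
    n_fp <- sum(e > e[a[k]] + delta[k])
    if (n_fp == 0L) {
      Fd[k] <- 0
      FDR[k] <- 0
    } else {
      b[k] <- S - n_fp + 1L
      Fd[k] <- psuf[b[k]]
      FDR[k] <- min(1, Fd[k] / N[k])
    }
  }
  structure(
    data.frame(U = U, delta = delta, a = a, b = b, N = N, F = Fd, FDR = FDR),
    x = x, S = S, chi2_null_max = emax, r = r,
    class = c("FdrCurve", "data.frame")
  )
}

#' Declare condition-associated tags at an FDR bound
#'
#' Chooses the smallest threshold on the curve whose estimated FDR is below
#' `alpha` and declares the tags at ranked positions `a..S` of the treatment
#' profile (the top `N` tags by treatment chi-square). The per-tag report
#' additionally records, for every tag, the FDR at the smallest grid
#' threshold at which the tag first enters a declared set (a step-function
#' q-value analogue; `NA` for tags never declared on the grid).
#'
#' @param p a [rank_profiles()] object.
#' @param curve a [scan_thresholds()] curve for `p`.
#' @param alpha FDR bound, default 0.05.
#' @return List with `declared` (character vector of tag ids, possibly
#'   empty), `delta`/`U`/`fdr`/`n` of the chosen threshold (`NA` if none),
#'   and `report`, a data.frame with columns `tag_id`, `chi2_treat`,
#'   `chi2_null`, `rank`, `declared`, `fdr`, `delta_at_declaration`.
#' @export
declare_tags <- function(p, curve, alpha = 0.05) {
  stopifnot(inherits(p, "RankedProfiles"), inherits(curve, "FdrCurve"))
  S <- p$S
  if (all(is.na(curve$FDR)))
    warning("treatment profile falls entirely inside the null profile; ",
            "no threshold has a defined FDR and no tags are declared")
  # per-tag first-declaration FDR: walk the grid from small to large delta
  fdr_tag <- rep(NA_real_, S)
  delta_tag <- rep(NA_real_, S)
  for (k in seq_len(nrow(curve))) {
    if (is.na(curve$a[k]) || is.na(curve$FDR[k])) next
    ranks <- seq.int(curve$a[k], S)
    new <- ranks[is.na(fdr_tag[ranks])]
    if (length(new) > 0L) {
      fdr_tag[new] <- curve$FDR[k]
      delta_tag[new] <- curve$delta[k]
    }
  }

  ok <- which(!is.na(curve$FDR) & curve$FDR < alpha)
  if (length(ok) == 0L) {
    if (any(!is.na(curve$FDR)))
      warning("no threshold achieves FDR < ", alpha, "; declaring no tags")
    chosen <- NULL
  } else {
    chosen <- ok[which.min(curve$delta[ok])]
  }
  declared_ranks <- if (is.null(chosen)) integer(0)
                    else seq.int(curve$a[chosen], S)
  declared <- p$treat_tags[declared_ranks]

  report <- data.frame(
    tag_id = p$treat_tags,
    chi2_treat = p$sorted_treat,
    chi2_null = NA_real_,
    rank = seq_len(S),
    declared = seq_len(S) %in% declared_ranks,
    fdr = fdr_tag,
    delta_at_declaration = delta_tag,
    stringsAsFactors = FALSE
  )
  # each tag's own (unranked) null chi-square, for reporting
  report$chi2_null <- p$sorted_null[match(report$tag_id, p$null_tags)]

  list(declared = declared,
       delta = if (is.null(chosen)) NA_real_ else curve$delta[chosen],
       U = if (is.null(chosen)) NA_real_ else curve$U[chosen],
       fdr = if (is.null(chosen)) NA_real_ else curve$FDR[chosen],
       n = length(declared),
       report = report)
}
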