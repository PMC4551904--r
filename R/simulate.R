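#' Simulation configuration
#'
#' Bundles the parameters of the count simulator: the effect-injection model
#' draws per-cell association masses from `Normal(normal_mean, normal_sd)`
#' truncated to positive values (defaults 100 and 50), and effects are
#' assigned to a fraction `effect_fraction` of simulated units.
#'
#' @param seed integer seed for all randomness of a simulation run.
#' @param r replicates per condition (>= 2).
#' @param effect_fraction fraction of units receiving an association effect,
#'   in (0, 1); typical study values are 0.10, 0.20, 0.30.
#' @param normal_mean,normal_sd parameters of the effect-mass normal draws.
#' @param template optional [tag_count_table()] used as moments source; when
#'   `NULL`, callers typically build one with [simulate_template()].
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed, r, effect_fraction,
                       normal_mean = 100, normal_sd = 50, template = NULL) {
  if (effect_fraction <= 0 || effect_fraction >= 1)
    stop("effect_fraction must be in (0, 1)")
  if (r < 2L) stop("r must be >= 2")
  structure(list(seed = as.integer(seed), r = as.integer(r),
                 effect_fraction = effect_fraction,
                 normal_mean = normal_mean, normal_sd = normal_sd,
                 template = template),
            class = "SimConfig")
}

#' Built-in template table generator
#'
#' Creates a realistic tag count table to serve as a moments source when no
#' real dataset is available: genes carry 2-4 tags, per-tag baseline means
#' are log-normal (median `exp(meanlog)` counts), and counts are negative
#' binomial with dispersion `size` around the baseline, identically in both
#' conditions (a null template: no condition effect). The defaults emulate
#' normalized bulk 3'-end tag counts: median per-tag count around 5 with a
#' wide log-normal spread and replicate overdispersion typical of
#' biological replicates, the regime in which the null chi-square profile
#' of a ~10^4-tag dataset spans roughly 0-7 (see the methods vignette).
#'
#' @param n_tags exact number of tags to generate (>= 2).
#' @param r replicates per condition.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters of per-tag baseline means.
#' @param size negative-binomial dispersion of template counts.
#' @return A [tag_count_table()].
#' @export
simulate_template <- function(n_tags = 60, r = 3, seed = 1,
                              meanlog = log(5), sdlog = 1, size = 3) {
  if (n_tags < 2L) stop("n_tags must be >= 2")
  set.seed(seed)
  sizes <- integer(0)
  rem <- as.integer(n_tags)
  while (rem > 0L) {
    if (rem == 1L) {                     # top up the previous gene
      sizes[length(sizes)] <- sizes[length(sizes)] + 1L
      rem <- 0L
    } else if (rem <= 4L) {
      sizes <- c(sizes, rem)
      rem <- 0L
    } else {
      z <- sample(2:4, 1L)
      sizes <- c(sizes, z)
      rem <- rem - z
    }
  }
  n_genes <- length(sizes)
  gene_id <- rep(sprintf("G%05d", seq_len(n_genes)), sizes)
  within <- unlist(lapply(sizes, seq_len))
  tag_id <- sprintf("%s.t%d", gene_id, within)
  mu <- stats::rlnorm(n_tags, meanlog = meanlog, sdlog = sdlog)
  n_lib <- 2L * r
  counts <- matrix(stats::rnbinom(n_tags * n_lib, mu = rep(mu, n_lib),
                                  size = size),
                   nrow = n_tags, ncol = n_lib)
  tags <- data.frame(tag_id = tag_id, gene_id = gene_id,
                     gene_name = gene_id, strand = "+",
                     position = within * 100, annotation = "synthetic",
                     stringsAsFactors = FALSE)
  libraries <- data.frame(
    library_id = c(sprintf("NS_%d", seq_len(r)), sprintf("TS_%d", seq_len(r))),
    condition = rep(1:2, each = r),
    replicate = rep(seq_len(r), 2L),
    stringsAsFactors = FALSE
  )
  tag_count_table(tags, counts, libraries)
}

#' Per-tag cell means and variances
#'
#' For every tag, the mean and (sample) variance over replicates of each of
#' the four cells of its 2x2 series: `(tag, rest-of-gene) x (rest condition,
#' stimulated condition)`. These moments parameterize the null simulator.
#'
#' @param t a [tag_count_table()] with all genes multi-tag and `r >= 2`.
#' @return List with `tag_id` and two `S x 4` matrices `means` and `vars`;
#'   cell column order is `(1,1), (1,2), (2,1), (2,2)` for (tag state,
#'   condition).
#' @export
estimate_cell_moments <- function(t) {
  stopifnot(inherits(t, "TagCountTable"))
  if (any(gene_sizes(t) < 2L))
    stop("single-tag genes present; apply filter_single_tag_genes() first")
  ar <- .tag_rest_arrays(t)
  if (ar$r < 2L) stop("r >= 2 replicates required for variance estimation")
  cell <- function(i, j) {
    m <- if (i == 1L) ar$tag[, j, , drop = FALSE] else ar$rest[, j, , drop = FALSE]
    matrix(m, nrow = dim(m)[1L])
  }
  means <- vars <- matrix(0, nrow = nrow(t$counts), ncol = 4L)
  k <- 0L
  for (i in 1:2) for (j in 1:2) {
    k <- k + 1L
    x <- cell(i, j)
    means[, k] <- rowMeans(x)
    vars[, k] <- rowSums((x - rowMeans(x))^2) / (ncol(x) - 1L)
  }
  colnames(means) <- colnames(vars) <- c("m11", "m12", "m21", "m22")
  list(tag_id = t$tags$tag_id, means = means, vars = vars, r = ar$r)
}

#' Generate a null (no-association) count table from template moments
#'
#' For each template tag one mean and one variance are chosen uniformly and
#' independently among its four cell means and four cell variances, and a
#' complete 2x2-by-replicate series is drawn from a negative binomial with
#' `mu` = the chosen mean and `size` = the chosen variance (the protocol's
#' literal parameterization; see the methods vignette). When the chosen
#' variance is degenerate for a negative binomial - non-finite, non-positive,
#' or at most the chosen mean (a negative binomial is always overdispersed,
#' so a target variance <= mean is unachievable) - the draw falls back to
#' `Poisson(mu)`. A consequence worth noting: in the non-degenerate branch
#' `size = v > mu` bounds the count variance by `mu + mu^2/v < 2*mu`, so
#' simulated counts are at most twice-Poisson dispersed. A tag whose chosen
#' mean is zero is emitted all-zero with a warning.
#'
#' Each simulated unit is materialized as a two-tag gene - tag `.s` holds the
#' tag-state row and tag `.r` the rest-of-gene row - so that rebuilding 2x2
#' tables from the output by gene complement reproduces exactly the tables
#' that were drawn, and units stay statistically independent of one another.
#'
#' @param moments output of [estimate_cell_moments()].
#' @param r replicates per condition of the simulated table.
#' @param seed integer seed.
#' @return A [tag_count_table()] with `2 * length(moments$tag_id)` tags.
#' @export
generate_null <- function(moments, r, seed) {
  r <- as.integer(r)
  if (r < 2L) stop("r must be >= 2")
  set.seed(seed)
  n_units <- length(moments$tag_id)
  pick_mean <- sample.int(4L, n_units, replace = TRUE)
  pick_var <- sample.int(4L, n_units, replace = TRUE)
  mu <- moments$means[cbind(seq_len(n_units), pick_mean)]
  vv <- moments$vars[cbind(seq_len(n_units), pick_var)]
  if (any(mu == 0))
    warning(sum(mu == 0), " unit(s) drew a zero mean and are emitted all-zero")
  use_nb <- is.finite(vv) & vv > mu & mu > 0
  n_lib <- 2L * r

  draw <- function() {                    # one library column for all units
    out <- numeric(n_units)
    if (any(use_nb))
      out[use_nb] <- stats::rnbinom(sum(use_nb), mu = mu[use_nb],
                                    size = vv[use_nb])
    if (any(!use_nb))
      out[!use_nb] <- stats::rpois(sum(!use_nb), lambda = mu[!use_nb])
    out
  }
  site <- matrix(0, n_units, n_lib)
  rest <- matrix(0, n_units, n_lib)
  for (l in seq_len(n_lib)) site[, l] <- draw()
  for (l in seq_len(n_lib)) rest[, l] <- draw()

  gene_id <- sprintf("U%05d", seq_len(n_units))
  tags <- data.frame(
    tag_id = c(rbind(paste0(gene_id, ".s"), paste0(gene_id, ".r"))),
    gene_id = rep(gene_id, each = 2L),
    gene_name = rep(moments$tag_id, each = 2L),  # provenance: template tag
    strand = "+",
    position = rep(c(100, 200), n_units),
    annotation = "simulated",
    stringsAsFactors = FALSE
  )
  counts <- matrix(0, 2L * n_units, n_lib)
  counts[seq(1L, 2L * n_units, by = 2L), ] <- site
  counts[seq(2L, 2L * n_units, by = 2L), ] <- rest
  libraries <- data.frame(
    library_id = c(sprintf("NS_%d", seq_len(r)), sprintf("TS_%d", seq_len(r))),
    condition = rep(1:2, each = r),
    replicate = rep(seq_len(r), 2L),
    stringsAsFactors = FALSE
  )
  tag_count_table(tags, counts, libraries)
}

#' Inject association effects into a null table
#'
#' A fraction `cfg$effect_fraction` of simulated units is selected without
#' replacement. For each selected unit, per-cell effect counts are
#' `n[i,j] = U[i,j] * N_i * N_j / N_total` with `N_i`, `N_j` independent
#' `Normal(normal_mean, normal_sd)` draws truncated positive by resampling,
#' `U[i,j]` an independent uniform on (0, 1] per cell, and `N_total` the sum
#' of the four normal masses. The per-cell uniforms are what makes the
#' injected table a genuine association effect: without them the effect
#' factorizes over rows and columns into an exact independence table with
#' zero chi-square (see the methods vignette). Each cell is bounded by
#' `N_i * N_j / N_total`. The rounded effect is added to every replicate of
#' cell `(i, j)`:
#' the unit's site tag receives the `i = 1` row and its rest tag the `i = 2`
#' row, so both rows of the unit's 2x2 series change consistently and both
#' tags of the unit are truly associated.
#'
#' @param null_table a table from [generate_null()] (two-tag units).
#' @param cfg a [sim_config()].
#' @return An object of class `SimTruth`: list with `table` (the effect
#'   table), `effect_tags` (tag ids of both tags of every effect unit) and
#'   `effect_sizes` (data.frame of the rounded per-cell additions).
#' @export
inject_effects <- function(null_table, cfg) {
  stopifnot(inherits(null_table, "TagCountTable"), inherits(cfg, "SimConfig"))
  tg <- null_table$tags
  site_rows <- grep("\\.s$", tg$tag_id)
  rest_rows <- grep("\\.r$", tg$tag_id)
  if (length(site_rows) == 0L || length(site_rows) != length(rest_rows))
    stop("inject_effects expects the two-tag unit structure of generate_null()")
  n_units <- length(site_rows)
  n_eff <- round(cfg$effect_fraction * n_units)
  if (n_eff < 1L) stop("effect_fraction times the number of units is below 1")

  set.seed(cfg$seed + 1L)
  units <- sort(sample.int(n_units, n_eff))
  rnorm_pos <- function(n) {
    x <- stats::rnorm(n, cfg$normal_mean, cfg$normal_sd)
    while (any(x <= 0))
      x[x <= 0] <- stats::rnorm(sum(x <= 0), cfg$normal_mean, cfg$normal_sd)
    x
  }
  Ni <- matrix(rnorm_pos(2L * n_eff), n_eff, 2L)   # tag-state masses
  Nj <- matrix(rnorm_pos(2L * n_eff), n_eff, 2L)   # condition masses
  U <- matrix(stats::runif(4L * n_eff), n_eff, 4L) # one uniform per cell
  Ntot <- rowSums(Ni) + rowSums(Nj)

  li <- .lib_index(null_table)
  cond_cols <- list(li$cond1, li$cond2)
  out <- null_table
  eff <- matrix(0, n_eff, 4L,
                dimnames = list(NULL, c("n11", "n12", "n21", "n22")))
  k <- 0L
  for (i in 1:2) for (j in 1:2) {
    k <- k + 1L
    add <- round(U[, k] * Ni[, i] * Nj[, j] / Ntot)
    eff[, k] <- add
    rows <- if (i == 1L) site_rows[units] else rest_rows[units]
    out$counts[rows, cond_cols[[j]]] <-
      out$counts[rows, cond_cols[[j]]] + add
  }
  effect_tags <- c(tg$tag_id[site_rows[units]], tg$tag_id[rest_rows[units]])
  structure(
    list(table = out,
         effect_tags = effect_tags,
         effect_sizes = data.frame(
           gene_id = tg$gene_id[site_rows[units]], eff,
           stringsAsFactors = FALSE)),
    class = "SimTruth")
}

#' True versus estimated FDR along a threshold curve
#'
#' For every grid threshold with a non-empty declared set, compares the
#' estimated FDR of [scan_thresholds()] with the true FDR computed from the
#' simulation truth labels: `true_F` is the number of declared tags that
#' carry no injected effect and `true_FDR = true_F / N` (0 when `N = 0`).
#'
#' @param truth a [inject_effects()] result (or any list with `effect_tags`).
#' @param p the [rank_profiles()] of the analyzed effect table.
#' @param curve the matching [scan_thresholds()] curve.
#' @return data.frame with columns `U`, `delta`, `N`, `F_est`, `est_FDR`,
#'   `true_F`, `true_FDR`, `T` (true positives, `N - true_F`).
#' @export
evaluate_calibration <- function(truth, p, curve) {
  stopifnot(inherits(p, "RankedProfiles"), inherits(curve, "FdrCurve"))
  S <- p$S
  is_fp <- !(p$treat_tags %in% truth$effect_tags)
  fp_suffix <- rev(cumsum(rev(as.numeric(is_fp))))   # false positives in a..S
  true_F <- ifelse(is.na(curve$a), 0, fp_suffix[pmax(curve$a, 1L)])
  true_F[is.na(curve$a)] <- 0
  true_FDR <- ifelse(curve$N > 0, true_F / curve$N, 0)
  data.frame(U = curve$U, delta = curve$delta, N = curve$N,
             F_est = curve$F, est_FDR = curve$FDR,
             true_F = true_F, true_FDR = true_FDR,
             T = curve$N - true_F)
}
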