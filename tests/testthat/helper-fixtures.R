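# fixtures and independent oracles shared across the test files

# small table: gene g1 has tags A,B; gene g2 has tags C,D,E; r replicates
make_toy_table <- function(r = 3, counts = NULL, seed = 42) {
  tags <- data.frame(
    tag_id = c("A", "B", "C", "D", "E"),
    gene_id = c("g1", "g1", "g2", "g2", "g2"),
    gene_name = c("G1", "G1", "G2", "G2", "G2"),
    strand = c("+", "+", "-", "-", "-"),
    position = c(100, 200, 10, 20, 30),
    annotation = "toy",
    stringsAsFactors = FALSE
  )
  libraries <- data.frame(
    library_id = c(sprintf("NS_%d", 1:r), sprintf("TS_%d", 1:r)),
    condition = rep(1:2, each = r),
    replicate = rep(1:r, 2),
    stringsAsFactors = FALSE
  )
  if (is.null(counts)) {
    set.seed(seed)
    counts <- matrix(rpois(5 * 2 * r, lambda = 20), nrow = 5)
  }
  tag_count_table(tags, counts, libraries)
}

# TwoByTwoSeries built directly from a 2 x 2 x r array of cells
make_series <- function(cells, tag_id = "s1") {
  structure(list(tag_id = tag_id, gene_id = "g", r = dim(cells)[3],
                 cells = cells, n_s = sum(cells)),
            class = "TwoByTwoSeries")
}

# ---- independent oracles ----------------------------------------------------

# generic (O - E)^2 / E Pearson chi-square; 0 on any zero marginal
oracle_chi2 <- function(tb) {
  rs <- rowSums(tb); cs <- colSums(tb); n <- sum(tb)
  if (any(rs == 0) || any(cs == 0)) return(0)
  e <- outer(rs, cs) / n
  sum((tb - e)^2 / e)
}

# brute-force BH step-up, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / seq.int(i, m)))
  }
  q
}

# two-sided Fisher exact p by full enumeration over fixed margins
oracle_fisher <- function(tb) {
  r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); n <- sum(tb)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(tb[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force threshold scan, position by position
oracle_scan <- function(sorted_treat, sorted_null, r, n_grid = 100, x = NULL) {
  S <- length(sorted_treat)
  emax <- sorted_null[S]
  if (is.null(x)) x <- (2 * r / emax)^2
  d <- sorted_treat - sorted_null
  U <- seq(0, n_grid) / n_grid
  out <- data.frame(U = U, delta = U * emax, a = NA_integer_, b = NA_integer_,
                    N = 0, F = 0, FDR = NA_real_)
  p <- ((sorted_null * seq_len(S)) / (emax * S))^x
  for (k in seq_along(U)) {
    delta <- out$delta[k]
    a <- NA_integer_
    for (cand in seq_len(S)) {          # smallest a with d > delta on a..S
      if (all(d[cand:S] > delta)) { a <- cand; break }
    }
    if (is.na(a)) next
    out$a[k] <- a
    out$N[k] <- S - a + 1
    b <- NA_integer_
    for (cand in seq_len(S)) {
      if (sorted_null[cand] - sorted_null[a] > delta) { b <- cand; break }
    }
    if (is.na(b)) {
      out$F[k] <- 0; out$FDR[k] <- 0
    } else {
      out$b[k] <- b
      out$F[k] <- sum(p[b:S])
      out$FDR[k] <- min(1, out$F[k] / out$N[k])
    }
  }
  out
}

# run the simulator end to end at a reduced scale
sim_pipeline <- function(seed, r = 3, effect_fraction = 0.1, n_units = 400,
                         n_grid = 100) {
  tpl <- simulate_template(n_tags = n_units, r = 3, seed = seed)
  mom <- estimate_cell_moments(tpl)
  nul <- suppressWarnings(generate_null(mom, r = r, seed = seed))
  truth <- inject_effects(nul, sim_config(seed = seed, r = r,
                                          effect_fraction = effect_fraction))
  prof <- chi_square_profile(truth$table)
  ranked <- rank_profiles(prof)
  curve <- scan_thresholds(ranked, r = r, n_grid = n_grid)
  list(template = tpl, null = nul, truth = truth, profile = prof,
       ranked = ranked, curve = curve,
       calibration = evaluate_calibration(truth, ranked, curve))
}
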