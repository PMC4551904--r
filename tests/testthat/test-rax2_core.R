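test_that("pearson_chi2 matches closed forms and rejects bad input", {
  expect_equal(pearson_chi2(matrix(c(10, 10, 10, 10), 2)), 0)
  expect_equal(pearson_chi2(matrix(c(20, 10, 10, 20), 2)), 60 * 300^2 / 30^4,
               tolerance = 1e-12)  # = 6.6667
  expect_equal(pearson_chi2(matrix(c(20, 10, 10, 20), 2)), 20 / 3,
               tolerance = 1e-12)
  expect_equal(pearson_chi2(matrix(c(5, 0, 0, 5), 2)), 10)
  expect_equal(pearson_chi2(matrix(c(0, 0, 3, 7), 2)), 0)   # zero marginal
  expect_error(pearson_chi2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(pearson_chi2(matrix(1, 3, 3)), "2x2")
})

test_that("pearson_chi2 equals the (O-E)^2/E oracle and is symmetric and homogeneous", {
  set.seed(101)
  for (i in 1:200) {
    tb <- matrix(runif(4, 0.1, 50), 2)
    expect_equal(pearson_chi2(tb), oracle_chi2(tb), tolerance = 1e-12)
    expect_equal(pearson_chi2(tb[2:1, ]), pearson_chi2(tb))   # row swap
    expect_equal(pearson_chi2(tb[, 2:1]), pearson_chi2(tb))   # column swap
    c0 <- runif(1, 0.1, 10)
    expect_equal(pearson_chi2(c0 * tb), c0 * pearson_chi2(tb),
                 tolerance = 1e-9)                             # degree 1
  }
})

test_that("build_two_by_two forms the gene complement correctly", {
  cnt <- rbind(c(1, 2, 3, 4, 5, 6),
               c(6, 5, 4, 3, 2, 1),
               c(1, 1, 1, 1, 1, 1),
               c(2, 2, 2, 2, 2, 2),
               c(3, 3, 3, 3, 3, 3))
  t <- make_toy_table(r = 3, counts = cnt)
  sA <- build_two_by_two(t, "A")
  expect_s3_class(sA, "TwoByTwoSeries")
  expect_equal(sA$cells[1, 1, ], c(1, 2, 3))     # A in NS replicates
  expect_equal(sA$cells[2, 1, ], c(6, 5, 4))     # complement = B
  expect_equal(sA$cells[1, 2, ], c(4, 5, 6))
  expect_equal(sA$n_s, sum(cnt[1:2, ]))
  # 3-tag gene: complement of C is D + E per library
  sC <- build_two_by_two(t, "C")
  expect_equal(sC$cells[2, 1, ], rep(5, 3))
  expect_equal(sC$cells[2, 2, ], rep(5, 3))
  # conservation: rows sum to gene totals per library
  expect_equal(sC$cells[1, 1, ] + sC$cells[2, 1, ], colSums(cnt[3:5, 1:3]))
  expect_error(build_two_by_two(t, "nope"), "unknown tag_id")
  t1 <- make_toy_table(r = 3)
  t1$tags$gene_id <- c("g1", "g1", "g2", "g2", "g3")  # E now single-tag
  expect_error(build_two_by_two(t1, "E"), "single-tag")
})

test_that("treatment_chi2 is the chi-square of the replicate-mean table", {
  cells1 <- array(c(20, 10, 10, 20), dim = c(2, 2, 1))
  expect_equal(treatment_chi2(make_series(cells1)), 20 / 3, tolerance = 1e-12)
  # identical replicates: equals a single replicate's chi-square
  cells3 <- array(rep(c(20, 10, 10, 20), 3), dim = c(2, 2, 3))
  expect_equal(treatment_chi2(make_series(cells3)), 20 / 3, tolerance = 1e-12)
  # heterogeneous replicates whose means form [[20,10],[10,20]]
  cells <- array(0, dim = c(2, 2, 3))
  cells[1, 1, ] <- c(10, 20, 30); cells[1, 2, ] <- c(10, 10, 10)
  cells[2, 1, ] <- c(5, 10, 15);  cells[2, 2, ] <- c(30, 20, 10)
  expect_equal(treatment_chi2(make_series(cells)), 20 / 3, tolerance = 1e-12)
})

test_that("null_chi2 schemes behave as documented", {
  # no within-condition variation -> 0 under both schemes
  cells <- array(rep(c(3, 9, 6, 18), 3), dim = c(2, 2, 3))
  s <- make_series(cells)
  expect_equal(null_chi2(s, "mean"), 0)
  expect_equal(null_chi2(s, "single"), 0)

  # proportional pair columns contribute 0
  c2 <- array(0, dim = c(2, 2, 2))
  c2[, 1, 1] <- c(3, 9); c2[, 1, 2] <- c(6, 18)      # proportional
  c2[, 2, 1] <- c(5, 5); c2[, 2, 2] <- c(5, 5)
  s2 <- make_series(c2)
  expect_equal(null_chi2(s2, "single", condition = 1, pair = c(1, 2)), 0)

  # r = 2: "mean" is the average of the two within-condition pair tables
  c3 <- array(0, dim = c(2, 2, 2))
  c3[, 1, 1] <- c(20, 10); c3[, 1, 2] <- c(10, 20)
  c3[, 2, 1] <- c(5, 0);   c3[, 2, 2] <- c(0, 5)
  s3 <- make_series(c3)
  chi_c1 <- pearson_chi2(cbind(c(20, 10), c(10, 20)))
  chi_c2 <- pearson_chi2(cbind(c(5, 0), c(0, 5)))
  expect_equal(null_chi2(s3, "mean"), mean(c(chi_c1, chi_c2)))
  expect_equal(null_chi2(s3, "single", condition = 2, pair = c(1, 2)), chi_c2)

  expect_error(null_chi2(make_series(array(1, c(2, 2, 1)))), "r >= 2")
  expect_error(null_chi2(s3, "single", condition = 3), "condition")
})

test_that("chi_square_profile agrees with the per-tag operations", {
  t <- make_toy_table(r = 3, seed = 7)
  for (scheme in c("single", "mean")) {
    prof <- chi_square_profile(t, null_scheme = scheme)
    pairs <- combn(3, 2)
    for (k in seq_len(nrow(prof))) {
      s <- build_two_by_two(t, prof$tag_id[k])
      expect_equal(prof$chi2_treat[k], treatment_chi2(s), tolerance = 1e-12)
      if (scheme == "mean") {
        expect_equal(prof$chi2_null[k], null_chi2(s, "mean"), tolerance = 1e-12)
      } else {
        cond <- (k - 1) %% 2 + 1
        pk <- ((k - 1) %/% 2) %% ncol(pairs) + 1
        expect_equal(prof$chi2_null[k],
                     null_chi2(s, "single", condition = cond,
                               pair = pairs[, pk]),
                     tolerance = 1e-12)
      }
    }
  }
  t_single <- t; t_single$tags$gene_id <- c("g1", "g1", "g2", "g2", "g3")
  expect_error(chi_square_profile(t_single), "single-tag")
})

test_that("chi-squares are invariant to condition-label and tag-state swaps", {
  t <- make_toy_table(r = 3, seed = 13)
  swapped <- t
  li <- rbind(t$libraries[t$libraries$condition == 2, ],
              t$libraries[t$libraries$condition == 1, ])
  li$condition <- rep(1:2, each = 3)
  swapped$libraries <- li
  swapped$counts <- t$counts[, c(4:6, 1:3)]
  colnames(swapped$counts) <- li$library_id
  p1 <- chi_square_profile(t, "mean")
  p2 <- chi_square_profile(swapped, "mean")
  expect_equal(p1$chi2_treat, p2$chi2_treat, tolerance = 1e-12)
  expect_equal(p1$chi2_null, p2$chi2_null, tolerance = 1e-12)
  # tag-state swap: in a 2-tag gene the two tags have identical chi-squares
  expect_equal(p1$chi2_treat[1], p1$chi2_treat[2], tolerance = 1e-12)
  expect_equal(p1$chi2_null[1], p1$chi2_null[2], tolerance = 1e-12)
})

test_that("scaling a whole gene's counts scales its treatment chi-square", {
  t <- make_toy_table(r = 3, seed = 5)
  t2 <- t
  g1 <- t$tags$gene_id == "g1"
  t2$counts[g1, ] <- 2.5 * t2$counts[g1, ]
  p1 <- chi_square_profile(t)
  p2 <- chi_square_profile(t2)
  expect_equal(p2$chi2_treat[g1], 2.5 * p1$chi2_treat[g1], tolerance = 1e-9)
})

test_that("rank_profiles sorts both profiles and keeps back-maps", {
  pairs <- data.frame(tag_id = c("a", "b"),
                      chi2_treat = c(5, 1), chi2_null = c(1, 3))
  p <- rank_profiles(pairs)
  expect_equal(p$sorted_treat, c(1, 5))
  expect_equal(p$sorted_null, c(1, 3))
  expect_equal(p$treat_tags, c("b", "a"))
  expect_equal(p$null_tags, c("a", "b"))
  expect_equal(p$chi2_null_max, 3)
  expect_equal(p$chi2_null_max, p$sorted_null[p$S])
  # back-map: every tag's rank is recoverable
  expect_equal(match(pairs$tag_id, p$treat_tags), c(2, 1))
  expect_error(rank_profiles(pairs[1, ]), "at least two")
  bad <- pairs; bad$chi2_null <- 0
  expect_error(rank_profiles(bad), "degenerate null")
})

test_that("scan_thresholds matches the brute-force oracle on small profiles", {
  set.seed(202)
  for (i in 1:15) {
    S <- 10
    pairs <- data.frame(tag_id = sprintf("t%02d", 1:S),
                        chi2_treat = round(runif(S, 0, 12), 2),
                        chi2_null = round(runif(S, 0.01, 6), 2))
    p <- rank_profiles(pairs)
    for (r in c(2, 3)) {
      got <- scan_thresholds(p, r = r, n_grid = 20)
      want <- oracle_scan(p$sorted_treat, p$sorted_null, r = r, n_grid = 20)
      expect_equal(got$a, want$a)
      expect_equal(got$b, want$b)
      expect_equal(got$N, want$N)
      expect_equal(got$F, want$F, tolerance = 1e-12)
      expect_equal(got$FDR, want$FDR, tolerance = 1e-12)
      # monotonicity along the grid
      expect_true(all(diff(got$N) <= 0))
      expect_true(all(diff(got$F) <= 1e-12))
    }
  }
})

test_that("scan_thresholds boundary behavior follows the definitions", {
  # every d > 0 at delta = 0 -> a = 1, N = S
  pairs <- data.frame(tag_id = letters[1:5],
                      chi2_treat = c(2, 3, 4, 5, 6),
                      chi2_null = c(1, 1.5, 2, 2.5, 3))
  p <- rank_profiles(pairs)
  cv <- scan_thresholds(p, r = 3)
  expect_equal(cv$a[1], 1L)
  expect_equal(cv$N[1], 5)
  # the top null position always has p = 1 regardless of x
  for (x in c(0, 0.5, 2)) {
    cvx <- scan_thresholds(p, r = 3, x = x)
    pS <- (p$sorted_null[5] * 5 / (p$chi2_null_max * 5))^x
    expect_equal(pS, 1)
  }
  # x = 0 forces p = 1 everywhere so F = S - b + 1
  cv0 <- scan_thresholds(p, r = 3, x = 0)
  k <- which(!is.na(cv0$b))
  expect_equal(cv0$F[k], 5 - cv0$b[k] + 1)
  expect_equal(attr(cv, "x"), (2 * 3 / 3)^2)
})

test_that("declare_tags picks the smallest qualifying threshold", {
  pairs <- data.frame(tag_id = sprintf("t%02d", 1:10),
                      chi2_treat = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 6, 8, 10),
                      chi2_null = c(0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.55, 0.6, 1))
  p <- rank_profiles(pairs)
  cv <- scan_thresholds(p, r = 3)
  d <- declare_tags(p, cv, alpha = 0.05)
  expect_equal(d$n, length(d$declared))
  k <- which(cv$delta == d$delta)
  expect_equal(d$n, cv$N[k])
  expect_true(all(d$declared %in% p$treat_tags[seq.int(cv$a[k], p$S)]))
  # alpha = 1: the largest defined declared set on the curve
  d1 <- declare_tags(p, cv, alpha = 1)
  expect_equal(d1$n, max(cv$N[!is.na(cv$FDR)]))
  # report consistency
  expect_equal(nrow(d$report), 10L)
  expect_equal(sum(d$report$declared), d$n)
  decl_rows <- d$report[d$report$declared, ]
  expect_true(all(!is.na(decl_rows$fdr)))
  expect_true(all(decl_rows$delta_at_declaration <= d$delta + 1e-12))
  # per-tag chi2_null is the tag's own value, not the rank-matched one
  expect_equal(d$report$chi2_null[match("t10", d$report$tag_id)], 1)
})

test_that("a treatment profile inside the null profile declares nothing", {
  pairs <- data.frame(tag_id = letters[1:6],
                      chi2_treat = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                      chi2_null = c(1, 2, 3, 4, 5, 6))
  p <- rank_profiles(pairs)
  cv <- scan_thresholds(p, r = 3)
  expect_true(all(is.na(cv$FDR)))
  expect_true(all(cv$N == 0))
  expect_warning(d <- declare_tags(p, cv, alpha = 0.05), "inside the null")
  expect_equal(d$n, 0)
  expect_equal(d$declared, character(0))
  expect_true(is.na(d$delta))
})
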