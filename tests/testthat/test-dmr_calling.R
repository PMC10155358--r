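test_that("BH step-up matches hand computation and handles edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  # monotone non-decreasing in p rank
  set.seed(1)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1) && all(q >= p))
})

test_that("BH agrees with the reference step-up implementation", {
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_lt(max(abs(bh_adjust(p) - stats::p.adjust(p, "BH"))), 1e-12)
  }
})

test_that("region test gives exact permutation p-values for small groups", {
  # 3v3 complete separation: only the two extreme assignments of 20
  tr <- test_region(c(0.9, 0.8, 0.85), c(0.2, 0.1, 0.15))
  expect_equal(tr$p, 0.1)
  expect_equal(tr$mean_diff, 0.7)
  expect_true(tr$exact)
  # identical groups: all assignments equally extreme under mid-ranks
  tr2 <- test_region(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(tr2$p, 1)
  expect_equal(tr2$mean_diff, 0)
  expect_error(test_region(0.5, c(0.1, 0.2)), "at least two")
})

test_that("exact p equals the exhaustive-permutation oracle, ties included", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n0 <- sample(2:5, 1)
    vals <- sample(seq(0, 1, by = 0.25), n1 + n0, replace = TRUE)  # many ties
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    expect_equal(test_region(x, y)$p, mwu_perm_oracle(x, y))
  }
})

test_that("exact and normal-approximation p agree closely at 6v6", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    p_exact <- test_region(x, y, exact_max_n = 12)$p
    p_approx <- test_region(x, y, exact_max_n = 0)$p
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("approximate branch matches wilcox.test with continuity correction", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(12, 0.3)     # no ties -> wilcox.test is valid
  p_pkg <- test_region(x, y)$p
  p_ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("segmentation keeps homogeneous runs whole and splits changepoints", {
  sites <- data.frame(chrom = "chr1", pos = seq(0, by = 50, length.out = 10),
                      diff = rep(0.3, 10), keep = TRUE)
  cand <- segment_candidates(sites)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_cpgs, 10)

  sites2 <- sites
  sites2$diff <- c(rep(0.4, 5), rep(0, 5))
  cand2 <- segment_candidates(sites2, seg_params(min_cpg = 5))
  expect_equal(nrow(cand2), 2)
  expect_equal(cand2$n_cpgs, c(5, 5))
  expect_equal(cand2$mean_diff, c(0.4, 0))
  # exhaustive breakpoint scan confirms the boundary is the best split
  scores <- sapply(1:9, function(k)
    abs(mean(sites2$diff[1:k]) - mean(sites2$diff[(k + 1):10])))
  expect_equal(which.max(scores), 5)

  # gap rule: two CpGs 1 kb apart cannot share a run
  sites3 <- data.frame(chrom = "chr1", pos = c(0, 1000), diff = 0.5,
                       keep = TRUE)
  cand3 <- segment_candidates(sites3, seg_params(max_gap = 300, min_cpg = 1))
  expect_equal(nrow(cand3), 2)

  expect_error(segment_candidates(data.frame(chrom = "chr1", pos = c(5, 2),
                                             diff = 0, keep = TRUE)),
               "sorted")
})

test_that("mark-specific significance gates follow the dual thresholds", {
  thr <- dmr_thresholds()
  # 0.25 difference at q = 0.01: significant as 5mC
  expect_true(dmr_significant(0.25, 0.01, "5mC", thr))
  # 0.15 difference: significant as 5hmC but not as 5mC
  expect_true(dmr_significant(0.15, 0.01, "5hmC", thr))
  expect_false(dmr_significant(0.15, 0.01, "5mC", thr))
  # q gate applies regardless of effect size
  expect_false(dmr_significant(0.5, 0.2, "5mC", thr))
  expect_true(dmr_significant(-0.25, 0.01, "BS", thr))
})

test_that("planted DMRs are called with the right mark, direction and span", {
  fix <- small_planted_cohort(seed = 23)
  pm <- estimate_cohort(fix$cohort)
  d5m <- call_dmrs(pm, mark = "5mC")
  d5h <- call_dmrs(pm, mark = "5hmC")
  eff <- fix$effects
  hits <- function(dmrs, r) {
    s <- dmrs[dmrs$significant, , drop = FALSE]
    any(s$chrom == r$chrom & s$start < r$end & s$end > r$start &
          s$direction == "hyper")
  }
  m_eff <- eff[eff$mark == "5mC", ]
  h_eff <- eff[eff$mark == "5hmC", ]
  expect_true(all(sapply(seq_len(nrow(m_eff)), function(i) hits(d5m, m_eff[i, ]))))
  expect_true(all(sapply(seq_len(nrow(h_eff)), function(i) hits(d5h, h_eff[i, ]))))
  # the 0.15 5hmC effect must not pass the 0.2 gate of the 5mC family
  expect_false(any(sapply(seq_len(nrow(h_eff)), function(i) hits(d5m, h_eff[i, ]))))
})

test_that("swapping case and control negates differences and keeps p-values", {
  fix <- small_planted_cohort(seed = 29, n_case = 5, n_control = 5)
  pm <- estimate_cohort(fix$cohort)
  g <- pm$groups
  fwd <- contrast_design("fwd", names(g)[g == "case"], names(g)[g == "control"])
  rev <- contrast_design("rev", names(g)[g == "control"], names(g)[g == "case"])
  d1 <- call_dmrs(pm, fwd, "5mC")
  d2 <- call_dmrs(pm, rev, "5mC")
  expect_equal(d2$mean_diff, -d1$mean_diff)
  expect_equal(d2$p, d1$p)
  expect_equal(d2$significant, d1$significant)
})

test_that("contrasts with fewer than two samples per group are rejected", {
  fix <- small_planted_cohort(seed = 2, n_case = 3, n_control = 3)
  pm <- estimate_cohort(fix$cohort)
  bad <- contrast_design("bad", names(pm$groups)[1], names(pm$groups)[2:4])
  expect_error(call_dmrs(pm, bad, "5mC"), "at least two")
})
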