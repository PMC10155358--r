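test_that("rank-based AUC matches hand values and the pair-counting oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  v <- c(0.7, 0.2, 0.9, 0.3, 0.4)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc(v, lab), auc_pair_oracle(v, lab))
  set.seed(8)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    vals <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(lab) || !any(lab)) next
    expect_equal(auc(vals, lab), auc_pair_oracle(vals, lab), tolerance = 1e-12)
  }
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC is the normalised Mann-Whitney U and flips with labels", {
  set.seed(3)
  x <- rnorm(7); y <- rnorm(5)
  tr <- test_region(x, y)
  a <- auc(c(x, y), c(rep(TRUE, 7), rep(FALSE, 5)))
  expect_equal(a, tr$U / (7 * 5))
  expect_equal(auc(c(x, y), !c(rep(TRUE, 7), rep(FALSE, 5))), 1 - a)
})

test_that("region means match direct recomputation and respect coverage", {
  fix <- small_planted_cohort(seed = 13, n_case = 4, n_control = 4)
  pm <- estimate_cohort(fix$cohort)
  regions <- fix$effects[, c("chrom", "start", "end")]
  mm <- region_sample_means(regions, pm, "5mC")
  for (i in seq_len(nrow(regions))) {
    rows <- pm$map$chrom == regions$chrom[i] &
      pm$map$pos >= regions$start[i] & pm$map$pos < regions$end[i]
    for (s in colnames(mm))
      expect_equal(mm[i, s], mean(pm$beta_ox[rows, s], na.rm = TRUE))
  }
  # simple two-CpG average
  pm2 <- pm
  pm2$beta_ox[, 1] <- NA
  pm2$beta_ox[which(rows)[1:2], 1] <- c(0.2, 0.4)
  mm2 <- region_sample_means(regions[nrow(regions), , drop = FALSE], pm2, "5mC")
  expect_equal(unname(mm2[1, 1]), 0.3)
  # a sample covering no region CpG gets a missing entry
  pm3 <- pm
  pm3$beta_ox[rows, 2] <- NA
  mm3 <- region_sample_means(regions[nrow(regions), , drop = FALSE], pm3, "5mC")
  expect_true(is.na(mm3[1, 2]))
  # region with no CpGs anywhere is dropped with warning
  expect_warning(
    region_sample_means(data.frame(chrom = "chrZ", start = 0L, end = 10L),
                        pm, "5mC"),
    "dropped")
})

test_that("strong planted DMRs pass the AUC screen and null regions do not", {
  fix <- small_planted_cohort(seed = 41, delta_5mc = 0.4,
                              coverage = coverage_spec(50, 8))
  pm <- estimate_cohort(fix$cohort)
  dmrs <- call_dmrs(pm, mark = "5mC")
  scr <- screen_biomarkers(dmrs, pm)
  eff <- fix$effects[fix$effects$mark == "5mC", ]
  ids <- sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end)
  planted <- rep(FALSE, nrow(dmrs))
  for (i in seq_len(nrow(eff)))
    planted <- planted | (dmrs$chrom == eff$chrom[i] &
                            dmrs$start < eff$end[i] & dmrs$end > eff$start[i])
  planted_ids <- ids[planted]
  expect_true(all(scr$passes_screen[scr$region %in% planted_ids]))
  # null candidate regions essentially never pass (screen requires
  # significance as well as AUC)
  expect_equal(sum(scr$passes_screen[!scr$region %in% planted_ids]), 0)
  # an impossible cutoff excludes everything
  scr2 <- screen_biomarkers(dmrs, pm, auc_cutoff = 1.01)
  expect_equal(sum(scr2$passes_screen), 0)
  # output is sorted by AUC descending
  expect_true(all(diff(scr$auc[!is.na(scr$auc)]) <= 1e-12))
})

test_that("exactly cancelling 5mC/5hmC shifts erase the BS signal", {
  ref <- simulate_reference(1, 60, seed = 77)
  eff <- plant_effects(ref$map, data.frame(mark = "5mC", delta = 0.3,
                                           coupling = -0.3, n = 1L))
  spec <- truth_spec(ref$map, ten_v_ten(), regions = eff,
                     coverage = coverage_spec(50, 8), seed = 77)
  pm <- estimate_cohort(simulate_counts(spec))
  cmp <- compare_signals(eff[1, c("chrom", "start", "end")], pm)
  expect_equal(cmp$signal, c("5mC", "5hmC", "BS"))
  expect_gt(cmp$auc[cmp$signal == "5mC"], 0.9)
  expect_lt(abs(cmp$mean_diff[cmp$signal == "BS"]), 0.08)
  expect_lt(cmp$auc[cmp$signal == "BS"], cmp$auc[cmp$signal == "5mC"])
})

test_that("a pure 5mC shift leaves BS and 5mC AUCs comparable", {
  ref <- simulate_reference(1, 60, seed = 78)
  eff <- plant_effects(ref$map, data.frame(mark = "5mC", delta = 0.35,
                                           coupling = 0, n = 1L))
  spec <- truth_spec(ref$map, ten_v_ten(), regions = eff,
                     coverage = coverage_spec(50, 8), seed = 78)
  pm <- estimate_cohort(simulate_counts(spec))
  cmp <- compare_signals(eff[1, c("chrom", "start", "end")], pm)
  expect_lt(abs(cmp$auc[cmp$signal == "BS"] - cmp$auc[cmp$signal == "5mC"]),
            0.15)
})

test_that("profile correlation behaves on identities and coupled effects", {
  prof <- stats::setNames(c(0.3, -0.2, 0.1, 0.25), paste0("r", 1:4))
  expect_equal(profile_correlation(prof, prof)$r, 1)
  expect_equal(profile_correlation(prof, -prof)$r, -1)
  expect_error(profile_correlation(prof[1:2], prof[1:2]), "fewer than 3")
  expect_error(profile_correlation(unname(prof), prof), "named")

  # coupled opposite-sign planted effects produce negative 5mC/5hmC
  # correlation of differential profiles over the planted regions
  ref <- simulate_reference(2, 300, seed = 55)
  deltas <- c(0.3, -0.3, 0.25, -0.25, 0.2, -0.2)
  eff <- do.call(rbind, lapply(seq_along(deltas), function(i)
    plant_effects(ref$map, data.frame(mark = "5mC", delta = deltas[i],
                                      coupling = -deltas[i] / 2, n = 1L),
                  skip = 1L)[1, ]))
  # move each effect onto its own cluster
  cls <- unique(ref$map$cluster)
  for (i in seq_along(deltas)) {
    p <- ref$map$pos[ref$map$cluster == cls[2 * i]]
    eff$chrom[i] <- ref$map$chrom[ref$map$cluster == cls[2 * i]][1]
    eff$start[i] <- min(p); eff$end[i] <- max(p) + 2L
  }
  spec <- truth_spec(ref$map, ten_v_ten(), regions = eff, seed = 56)
  pm <- estimate_cohort(simulate_counts(spec))
  g <- pm$groups
  mm_m <- region_sample_means(eff[, c("chrom", "start", "end")], pm, "5mC")
  mm_h <- region_sample_means(eff[, c("chrom", "start", "end")], pm, "5hmC")
  dm <- rowMeans(mm_m[, g == "case"]) - rowMeans(mm_m[, g == "control"])
  dh <- rowMeans(mm_h[, g == "case"]) - rowMeans(mm_h[, g == "control"])
  pc <- profile_correlation(dm, dh)
  expect_lt(pc$r, 0)
  expect_equal(pc$n, length(deltas))
})

test_that("screening an empty DMR set returns an empty report", {
  fix <- small_planted_cohort(seed = 2, n_case = 3, n_control = 3)
  pm <- estimate_cohort(fix$cohort)
  d0 <- data.frame(chrom = character(), start = integer(), end = integer())
  scr <- screen_biomarkers(d0, pm, signal = "5mC")
  expect_s3_class(scr, "biomarker_screen")
  expect_equal(nrow(scr), 0)
})
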