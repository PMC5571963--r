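# Landscape statistics: percentile ranks, quota curves, tail tests,
# rank tests, class summaries, binder-group selection.

test_that("percentile ranks follow the midpoint formula with stable ties", {
  land <- percentile_rank(toy_enrichment(c(1, 2, 3, 4)))
  expect_equal(land$percentile, c(12.5, 37.5, 62.5, 87.5))
  # reversing the input order changes nothing
  rev_in <- toy_enrichment(c(4, 3, 2, 1), ids = c("g004", "g003", "g002", "g001"))
  expect_equal(percentile_rank(rev_in)$gene_id, land$gene_id)
  # all-equal ratios fall back to id order
  tied <- percentile_rank(toy_enrichment(c(2, 2, 2), ids = c("c", "a", "b")))
  expect_equal(tied$gene_id, c("a", "b", "c"))
  expect_error(percentile_rank(toy_enrichment(1)), "at least 2")
})

test_that("quota curve matches a brute-force window count", {
  set.seed(404)
  cls <- c(rep("MPR", 10), rep("CPR", 90))
  ratios <- c(runif(10, 10, 20), runif(90, 0, 5))  # MPRs occupy the top decile
  land <- percentile_rank(toy_enrichment(ratios, classes = cls))
  qc <- quota_curve(land, window_width = 10, step = 1)
  # brute-force oracle for every MPR window value
  for (ct in c(0, 37, 50, 85, 95, 100)) {
    lo <- max(0, ct - 5); hi <- min(100, ct + 5)
    inw <- land$percentile >= lo & land$percentile <= hi
    want <- sum(inw & land$loc_class == "MPR") / sum(inw)
    got <- qc$quota[qc$center == ct & qc$class == "MPR"]
    expect_equal(got, want, info = paste("center", ct))
  }
  # the top window is pure MPR, windows below the 80th percentile pure CPR
  expect_equal(qc$quota[qc$center == 100 & qc$class == "MPR"], 1.0)
  expect_true(all(qc$quota[qc$center < 80 & qc$class == "MPR"] == 0))
  # class = all genes -> quota identically 1
  all_one <- quota_curve(land, classes = setNames(rep("x", 100), land$gene_id))
  expect_true(all(all_one$quota == 1))
  expect_error(quota_curve(land, window_width = 150), "window_width")
})

test_that("decile class counts sum to class size", {
  s <- small_sim(seed = 21)
  land <- sim_landscape(s)
  dc <- decile_counts(land)
  for (cl in c("MPR", "CPR")) {
    expect_equal(sum(dc[[cl]]), sum(land$loc_class == cl))
  }
})

test_that("hypergeometric tail p equals exhaustive enumeration (derived case)", {
  # N=10, n=4, K=5, k=4: 6 of the 252 possible tails hold >= 4 class members
  cls <- c(rep("MPR", 4), rep("CPR", 6))
  ratios <- c(7:10, 1:6)  # the 4 MPRs are the top 4
  land <- percentile_rank(toy_enrichment(ratios, classes = cls))
  tt <- tail_overrepresentation(land, "MPR", tail_fraction = 0.5, side = "top")
  expect_equal(tt$K, 5)
  expect_equal(tt$k, 4)
  expect_equal(tt$p_value, 6 / 252, tolerance = 1e-12)
  expect_equal(tt$p_value, hyper_enum_p(4, 10, 4, 5), tolerance = 1e-12)
  # k = 0 -> p = 1
  land2 <- percentile_rank(toy_enrichment(c(1:4, 7:10, 5, 6),
                                          classes = cls))
  tt2 <- tail_overrepresentation(land2, "MPR", 0.2, "top")
  expect_equal(tt2$k, 0)
  expect_equal(tt2$p_value, 1)
  expect_error(tail_overrepresentation(land, "nope", 0.3, "top"), "nope")
  expect_error(tail_overrepresentation(land, "MPR", 1.2, "top"), "tail_fraction")
})

test_that("tail p decreases monotonically in k at fixed N, n, K", {
  ps <- vapply(0:5, function(k) fracseq:::hyper_upper_tail(k, 20, 5, 8),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment reproduces the step-up hand example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  expect_true(all(bh_fdr(c(0.001, 0.5)) >= c(0.001, 0.5)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney matches enumeration, symmetry and the null", {
  mw <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(mw$p_value, mw_enum_p(c(1, 2), c(3, 4)), tolerance = 1e-12)
  # swapping groups maps U -> n1*n2 - U and keeps p
  mw2 <- mann_whitney_test(c(3, 4), c(1, 2))
  expect_equal(mw2$statistic, 2 * 2 - mw$statistic)
  expect_equal(mw2$p_value, mw$p_value)
  # identical samples are null
  expect_gte(mann_whitney_test(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_error(mann_whitney_test(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney exact p equals full permutation enumeration", {
  set.seed(99)
  for (n1 in c(2, 3, 5)) {
    for (n2 in c(2, 4, 6)) {
      vals <- sample(seq_len(50), n1 + n2)  # distinct -> no ties
      a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
      expect_equal(mann_whitney_test(a, b)$p_value, mw_enum_p(a, b),
                   tolerance = 1e-12, info = paste(n1, n2))
    }
  }
})

test_that("KS statistic behaves as a rank statistic", {
  expect_equal(ks_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_test(c(1, 2), c(3, 4))$statistic, 1)
  # invariant under a common strictly monotone transform
  set.seed(5)
  a <- rnorm(20); b <- rnorm(25, 1)
  k1 <- ks_test(a, b)
  k2 <- ks_test(exp(a), exp(b))
  expect_equal(k1$statistic, k2$statistic)
  expect_equal(k1$p_value, k2$p_value)
  expect_error(ks_test(numeric(0), 1), "non-empty")
})

test_that("class summary reports medians, means and percent change", {
  cls <- c("MPR", "MPR", "CPR", "CPR")
  land <- percentile_rank(toy_enrichment(c(1, 3, 1, 1), classes = cls))
  cs <- class_summary(land)
  expect_equal(cs$median_ratio[cs$class == "MPR"], 2)
  expect_equal(cs$mean_ratio[cs$class == "MPR"], 2)
  # all-gene mean is 1.5; MPR mean 2 -> +33.3%
  expect_equal(cs$pct_change_vs_all[cs$class == "MPR"], 100 * (2 - 1.5) / 1.5)
  # a class equal to all genes has zero percent change
  one <- class_summary(land, classes = setNames(rep("x", 4), land$gene_id))
  expect_equal(one$pct_change_vs_all, 0)
  expect_equal(class_summary(percentile_rank(
    toy_enrichment(c(1, 2, 4), classes = rep("A", 3))))$median_ratio, 2)
})

test_that("binder-group selection takes the bottom tail and an equal top group", {
  set.seed(17)
  n <- 100
  cls <- rep(c("MPR", "CPR"), each = 50)
  ratios <- runif(n)
  binding <- toy_enrichment(ratios, classes = cls)
  g <- select_binder_groups(binding, class = "MPR", weak_fraction = 0.3)
  land <- percentile_rank(binding)
  bottom <- land$gene_id[land$rank <= 30]
  expect_setequal(g$weak, intersect(bottom, land$gene_id[land$loc_class == "MPR"]))
  expect_equal(length(g$strong), length(g$weak))
  expect_length(intersect(g$weak, g$strong), 0)
  # strong binders really come from the top of the list
  top_ranks <- land$rank[match(g$strong, land$gene_id)]
  expect_true(all(top_ranks > stats::median(land$rank)))
  # overlap sets shrink the groups asymmetrically
  drop1 <- setdiff(land$gene_id, g$weak[1])
  drop3 <- setdiff(land$gene_id, g$strong[1:3])
  g2 <- select_binder_groups(binding, "MPR", 0.3,
                             overlap_sets = list(drop1, drop3))
  expect_equal(length(g2$weak), length(g$weak) - 1)
  expect_equal(length(g2$strong), length(g$strong) - 3)
  expect_error(select_binder_groups(binding, "XPR"), "XPR")
})

test_that("MW detects a planted class effect on simulated landscapes", {
  s <- small_sim(n_mpr = 30, n_cpr = 120, mpr_membrane = 2,
                 library_size = 1e6, seed = 77)
  land <- sim_landscape(s)
  mw <- mann_whitney_test(land$ratio[land$loc_class == "MPR"],
                          land$ratio[land$loc_class == "CPR"])
  expect_lt(mw$p_value, 1e-4)
  tt <- tail_overrepresentation(land, "MPR", 0.3, "top")
  expect_lt(tt$p_value, 1e-3)
})
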