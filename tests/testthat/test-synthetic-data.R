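# Synthetic-data generator: catalogs, counts, qPCR panels, planted motifs.

test_that("gene catalog honours the design and is deterministic", {
  d <- sim_design(n_mpr = 2, n_cpr = 3, n_other = 1, seed = 7)
  cat1 <- build_gene_catalog(d)
  expect_equal(nrow(cat1), 6)
  expect_equal(sum(cat1$loc_class == "MPR"), 2)
  expect_equal(sum(cat1$loc_class == "CPR"), 3)
  expect_false(anyDuplicated(cat1$gene_id) > 0)
  expect_true(all(cat1$cds_length >= 100 & cat1$cds_length <= 6000))
  expect_identical(cat1, build_gene_catalog(d))

  # degenerate: a class may be empty without error
  d0 <- sim_design(n_mpr = 0, n_cpr = 3, n_other = 1, seed = 7)
  expect_equal(sum(build_gene_catalog(d0)$loc_class == "MPR"), 0)
})

test_that("invalid designs fail with the offending field named", {
  expect_error(sim_design(n_mpr = -1), "n_mpr")
  expect_error(sim_design(rrna_load = 1.0), "rrna_load")
  expect_error(sim_design(fractions = c("membrane", "70S")), "extract")
  expect_error(sim_design(n_replicates = 0), "n_replicates")
})

test_that("count simulation is reproducible and respects truth coverage", {
  s <- small_sim(seed = 42)
  s2 <- small_sim(seed = 42)
  expect_identical(s$counts$counts, s2$counts$counts)
  # missing fraction in truth -> consistency error
  tr_bad <- s$truth
  tr_bad$multipliers <- tr_bad$multipliers[, "extract", drop = FALSE]
  expect_error(simulate_fraction_counts(s$catalog, s$design, tr_bad),
               "missing fractions")
})

test_that("null multipliers give equal per-gene means across fractions", {
  d <- sim_design(n_mpr = 10, n_cpr = 30, n_other = 2,
                  fractions = c("extract", "membrane"),
                  n_replicates = 1, library_size = 1e5,
                  rrna_load = c(extract = 0.3, membrane = 0.3),
                  dispersion = 0.02, seed = 9)
  catal <- build_gene_catalog(d)
  tr <- make_sim_truth(catal, d, class_multipliers = list(), gene_sd = 0)
  # Monte-Carlo over 200 replicate draws via the seed substream
  tot_e <- tot_m <- numeric(nrow(catal))
  for (r in 1:200) {
    d_r <- d; d_r$seed <- 10000L + r
    cm <- simulate_fraction_counts(catal, d_r, tr)
    tot_e <- tot_e + cm$counts[, "extract_rep1"]
    tot_m <- tot_m + cm$counts[, "membrane_rep1"]
  }
  mrna <- catal$feature_class == "mRNA"
  ratio <- tot_m[mrna] / tot_e[mrna]
  expect_true(all(abs(log2(ratio)) < 0.25))
})

test_that("a planted multiplier is recovered by empirical count ratios", {
  # Monte-Carlo oracle: mean(membrane)/mean(extract) over 200 seeds
  d <- sim_design(n_mpr = 5, n_cpr = 15, n_other = 2,
                  fractions = c("extract", "membrane"), n_replicates = 1,
                  library_size = 1e6,
                  rrna_load = c(extract = 0.3, membrane = 0.3),
                  dispersion = 0.05, seed = 3)
  catal <- build_gene_catalog(d)
  tr <- make_sim_truth(catal, d,
                       class_multipliers = list(MPR = c(membrane = 4)),
                       gene_sd = 0)
  tot_e <- tot_m <- numeric(nrow(catal))
  for (r in 1:200) {
    d_r <- d; d_r$seed <- 20000L + r
    cm <- simulate_fraction_counts(catal, d_r, tr)
    tot_e <- tot_e + cm$counts[, "extract_rep1"]
    tot_m <- tot_m + cm$counts[, "membrane_rep1"]
  }
  g <- catal$gene_id[catal$loc_class == "MPR"][1]
  i <- match(g, catal$gene_id)
  # the multiplier acts on concentration; compositional dilution by the
  # other mRNAs is cancelled by comparing to a null CPR gene
  j <- match(catal$gene_id[catal$loc_class == "CPR"][1], catal$gene_id)
  emp <- (tot_m[i] / tot_e[i]) / (tot_m[j] / tot_e[j])
  expect_lt(abs(log2(emp) - log2(4)), 0.15)
})

test_that("rrna_load sets the non-mRNA read share of a library", {
  d <- sim_design(n_mpr = 10, n_cpr = 10, n_other = 3,
                  fractions = c("extract", "70S"), n_replicates = 1,
                  library_size = 1e6,
                  rrna_load = c(extract = 0.5, "70S" = 0.99),
                  dispersion = 0, seed = 4)
  catal <- build_gene_catalog(d)
  tr <- make_sim_truth(catal, d, class_multipliers = list(), gene_sd = 0)
  cm <- simulate_fraction_counts(catal, d, tr)
  mrna <- catal$feature_class == "mRNA"
  share <- sum(cm$counts[mrna, "70S_rep1"]) / sum(cm$counts[, "70S_rep1"])
  expect_lt(abs(share - 0.01), 0.003)
})

test_that("adding a library does not perturb existing substreams", {
  d2 <- sim_design(n_mpr = 5, n_cpr = 10, n_other = 2,
                   fractions = c("extract", "membrane"), n_replicates = 1,
                   rrna_load = c(extract = 0.3, membrane = 0.3),
                   library_size = 1e5, seed = 6)
  d3 <- sim_design(n_mpr = 5, n_cpr = 10, n_other = 2,
                   fractions = c("extract", "membrane"), n_replicates = 2,
                   rrna_load = c(extract = 0.3, membrane = 0.3),
                   library_size = 1e5, seed = 6)
  catal <- build_gene_catalog(d2)
  tr <- make_sim_truth(catal, d2, gene_sd = 0)
  c2 <- simulate_fraction_counts(catal, d2, tr)
  c3 <- simulate_fraction_counts(catal, d3, tr)
  # replicate 1 libraries are identified by sample id in both runs
  shared <- intersect(colnames(c2$counts), colnames(c3$counts))
  expect_gt(length(shared), 0)
  for (s in shared) expect_identical(c2$counts[, s], c3$counts[, s])
})

test_that("noise-free qPCR panels invert the mass-balance formulas exactly", {
  P <- matrix(c(0.2, 0.3, 0.5,
                0.05, 0.15, 0.80), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("free", "70S", "pellet")))
  mass <- c(extract = 40, free = 10, "70S" = 20, pellet = 10)
  q <- simulate_qpcr_panel(P, mass, ct_sd = 0)
  rec <- qpcr_portions(q)
  expect_equal(rec[rownames(P), colnames(P)], P, tolerance = 1e-12)
  # exhaustive disjoint fractions conserve mass
  expect_equal(unname(rowSums(rec)), c(1, 1), tolerance = 1e-9)
  # portion 0.5 at equal masses means exactly one extra cycle
  q1 <- simulate_qpcr_panel(matrix(0.5, 1, 1, dimnames = list("g", "f")),
                            c(extract = 10, f = 10), ct_extract = 20)
  cts <- setNames(q1$ct, q1$sample)
  expect_equal(cts[["f"]] - cts[["extract"]], 1)
})

test_that("qPCR simulation rejects nonpositive masses", {
  P <- matrix(0.5, 1, 1, dimnames = list("g", "f"))
  expect_error(simulate_qpcr_panel(P, c(extract = 0, f = 10)), "positive")
})

test_that("motif planting produces exactly the recorded ground truth", {
  d <- sim_design(n_mpr = 3, n_cpr = 3, n_other = 0, seed = 11)
  catal <- build_gene_catalog(d)
  rules <- compile_builtin_rules()
  pc <- matrix(0L, nrow(catal), 5,
               dimnames = list(catal$gene_id, names(rules)))
  pc["mpr_0001", "R1"] <- 3L
  pc["mpr_0002", "R4"] <- 2L
  pc["cpr_0001", "R3"] <- 2L
  sim <- simulate_transcripts_with_motifs(catal, rules, pc, seed = 5)
  found <- scan_sequences(sim$sequences, rules)
  for (rid in names(rules)) {
    tru <- sim$truth[sim$truth$rule_id == rid, c("gene_id", "start", "end")]
    got <- found[found$rule_id == rid, c("gene_id", "start", "end")]
    o1 <- order(tru$gene_id, tru$start); o2 <- order(got$gene_id, got$start)
    expect_equal(unname(as.matrix(got[o2, 2:3])), unname(as.matrix(tru[o1, 2:3])),
                 info = rid)
    expect_identical(got$gene_id[o2], tru$gene_id[o1])
  }
  # plant 0 everywhere -> scanner reports 0 for every gene
  sim0 <- simulate_transcripts_with_motifs(catal, rules, seed = 5)
  expect_equal(nrow(scan_sequences(sim0$sequences, rules)), 0)
})

test_that("infeasible planting raises a capacity error", {
  catal <- data.frame(gene_id = "g1", cds_length = 30L,
                      loc_class = "MPR", feature_class = "mRNA",
                      stringsAsFactors = FALSE)
  rules <- compile_builtin_rules()
  pc <- matrix(c(5L, 0L, 0L, 0L, 0L), 1, 5,
               dimnames = list("g1", names(rules)))
  expect_error(simulate_transcripts_with_motifs(catal, rules, pc, seed = 1),
               "cannot plant")
})
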