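# RPKM, feature filtering, enrichment ratios, qPCR quantities.

make_counts <- function(m, fractions = colnames(m)) {
  count_matrix(m, data.frame(sample_id = colnames(m), fraction = fractions,
                             replicate = 1L, stringsAsFactors = FALSE))
}

toy_catalog <- function(ids, lens, feat = "mRNA", loc = "CPR") {
  data.frame(gene_id = ids, cds_length = lens,
             loc_class = rep_len(loc, length(ids)),
             feature_class = rep_len(feat, length(ids)),
             stringsAsFactors = FALSE)
}

test_that("feature filtering keeps mRNA rows and recomputes nothing else", {
  m <- matrix(1:10, nrow = 5, dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  cm <- make_counts(m, c("extract", "membrane"))
  catal <- toy_catalog(paste0("g", 1:5), rep(500L, 5),
                       feat = c("mRNA", "mRNA", "mRNA", "rRNA", "tRNA"))
  out <- filter_feature_classes(cm, catal)
  expect_equal(rownames(out$counts), paste0("g", 1:3))
  # all-mRNA input is the identity
  catal2 <- toy_catalog(paste0("g", 1:5), rep(500L, 5))
  expect_identical(filter_feature_classes(cm, catal2)$counts, cm$counts)
  # no mRNA at all -> empty matrix with a warning
  catal3 <- toy_catalog(paste0("g", 1:5), rep(500L, 5), feat = "rRNA")
  expect_warning(out3 <- filter_feature_classes(cm, catal3), "no rows")
  expect_equal(nrow(out3$counts), 0)
  # unknown gene -> consistency error naming it
  expect_error(filter_feature_classes(cm, catal[-1, ]), "g1")
})

test_that("RPKM matches its definition and is scale invariant", {
  m <- matrix(c(100L, 999900L), nrow = 2,
              dimnames = list(c("a", "b"), "s1"))
  catal <- toy_catalog(c("a", "b"), c(1000L, 99990L))
  rp <- compute_rpkm(make_counts(m, "extract"), catal)
  expect_equal(rp["a", "s1"], 100)  # 100 * 1e9 / (1000 * 1e6)
  # doubling every count leaves RPKM unchanged
  rp2 <- compute_rpkm(make_counts(m * 2L, "extract"), catal)
  expect_equal(rp2, rp)
  # zero count -> zero RPKM
  m0 <- m; m0["a", 1] <- 0L
  expect_equal(compute_rpkm(make_counts(m0, "extract"), catal)["a", "s1"], 0)
  # zero-total sample is undefined
  mz <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_error(compute_rpkm(make_counts(mz, "extract"), catal), "zero total")
})

test_that("RPKM reconstruction reproduces the input counts", {
  s <- small_sim(seed = 8)
  fl <- filter_feature_classes(s$counts, s$catalog)
  rp <- compute_rpkm(fl, s$catalog)
  len <- s$catalog$cds_length[match(rownames(fl$counts), s$catalog$gene_id)]
  tot <- colSums(fl$counts)
  rebuilt <- sweep(rp * len / 1e9, 2, tot, "*")
  expect_equal(rebuilt, fl$counts + 0, tolerance = 1e-6)
})

test_that("enrichment ratios follow the definition and the drop contract", {
  rp <- matrix(c(4, 2, 0.5, 2, 2, 8), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("extract", "membrane")))
  # identical columns -> all ratios 1
  rp_eq <- cbind(extract = rp[, 1], membrane = rp[, 1])
  en <- enrichment_ratio(rp_eq, "membrane", "extract", min_rpkm = 0.1)
  expect_true(all(en$ratio == 1))
  # gene below threshold in the reference is dropped and reported
  en2 <- enrichment_ratio(rp, "membrane", "extract", min_rpkm = 1)
  expect_false("c" %in% en2$gene_id)
  drops <- attr(en2, "dropped")
  expect_equal(drops$gene_id, "c")
  expect_equal(drops$reason, "reference")
  expect_equal(en2[en2$gene_id == "b", "ratio"], 1)
  # fraction == reference is a parameter error
  expect_error(enrichment_ratio(rp, "extract", "extract"), "differ")
  # nothing passing is an error, not an empty result
  expect_error(enrichment_ratio(rp, "membrane", "extract", min_rpkm = 100),
               "no gene")
})

test_that("enrichment ratio is invariant under per-sample count rescaling", {
  s <- small_sim(seed = 12)
  fl <- filter_feature_classes(s$counts, s$catalog)
  po <- pool_replicates(fl)
  rp1 <- compute_rpkm(po, s$catalog)
  scaled <- po
  scaled$counts[, "membrane"] <- scaled$counts[, "membrane"] * 3L
  rp2 <- compute_rpkm(scaled, s$catalog)
  e1 <- enrichment_ratio(rp1, "membrane", "extract", min_rpkm = 0)
  e2 <- enrichment_ratio(rp2, "membrane", "extract", min_rpkm = 0)
  expect_equal(e2$ratio, e1$ratio, tolerance = 1e-12)
})

test_that("true multipliers are recovered from deep synthetic data", {
  # 100 genes with multipliers spread over [0.25, 8] among null ballast;
  # estimator = ratio / median(all ratios) (median-of-ratios rescaling
  # removes the compositional dilution shared by every gene)
  d <- sim_design(n_mpr = 100, n_cpr = 400, n_other = 4,
                  fractions = c("extract", "membrane"), n_replicates = 3,
                  library_size = 5e6,
                  rrna_load = c(extract = 0.5, membrane = 0.5),
                  dispersion = 0.01, seed = 31)
  catal <- build_gene_catalog(d)
  tr <- make_sim_truth(catal, d, class_multipliers = list(), gene_sd = 0)
  mpr <- catal$gene_id[catal$loc_class == "MPR"]
  mults <- 2^seq(-2, 3, length.out = length(mpr))
  tr$multipliers[mpr, "membrane"] <- mults
  counts <- simulate_fraction_counts(catal, d, tr)
  rp <- compute_rpkm(pool_replicates(filter_feature_classes(counts, catal)),
                     catal)
  en <- enrichment_ratio(rp, "membrane", "extract")
  est <- en$ratio / stats::median(en$ratio)
  err <- abs(log2(est[match(mpr, en$gene_id)]) - log2(mults))
  expect_lt(stats::median(err, na.rm = TRUE), 0.15)
})

test_that("overlap gene set is the intersection with class counts", {
  t1 <- toy_enrichment(c(1, 2, 3), ids = c("a", "b", "c"))
  t2 <- toy_enrichment(c(1, 2, 3), ids = c("b", "c", "d"))
  expect_equal(overlap_gene_set(list(t1, t2)), c("b", "c"))
  expect_equal(overlap_gene_set(list(t1)), c("a", "b", "c"))
  t3 <- toy_enrichment(c(1, 2), ids = c("x", "y"))
  expect_warning(ov <- overlap_gene_set(list(t1, t3)), "empty")
  expect_equal(length(ov), 0)
})

test_that("qPCR relative concentration and portion formulas", {
  expect_equal(qpcr_relative_concentration(20, 18), 4)
  expect_equal(qpcr_relative_concentration(20, 20), 1)
  expect_equal(qpcr_relative_concentration(18, 20), 0.25)
  expect_error(qpcr_relative_concentration(Inf, 20), "finite")
  expect_equal(qpcr_fraction_portion(4, 10, 40), 1)
  expect_equal(qpcr_fraction_portion(1, 10, 10), 1)
  # reference-gene normalization divides by the control's relative conc
  expect_equal(qpcr_fraction_portion(4, 10, 40, ref_rel_conc = 2), 0.5)
  expect_error(qpcr_fraction_portion(1, -1, 10), "positive")
})

test_that("standard-curve QC enforces slope and R-squared bounds", {
  d <- c(0, -1, -2, -3)
  # perfect two-fold chemistry: slope exactly -log2(10)
  qc <- standard_curve_qc(d, 20 - log2(10) * d)
  expect_equal(qc$slope, -log2(10), tolerance = 1e-9)
  expect_true(qc$pass)
  # slope out of range fails
  expect_false(standard_curve_qc(d, 20 - 2.5 * d)$pass)
  # in-range slope but poor fit fails on R-squared
  cts <- 20 - log2(10) * d + c(0, 0.45, -0.45, 0)
  qc3 <- standard_curve_qc(d, cts)
  expect_lt(qc3$r_squared, 0.995)
  expect_false(qc3$pass)
  expect_error(standard_curve_qc(c(0, -1), c(20, 23)), ">= 3")
})

test_that("replicate pooling sums counts and flags inconsistency", {
  m <- matrix(c(10L, 20L, 12L, 18L, 5L, 40L), nrow = 2,
              dimnames = list(c("a", "b"),
                              c("e_rep1", "e_rep2", "m_rep1")))
  cm <- count_matrix(m, data.frame(
    sample_id = colnames(m), fraction = c("extract", "extract", "membrane"),
    replicate = c(1L, 2L, 1L), stringsAsFactors = FALSE))
  po <- pool_replicates(cm, min_spearman = NA)
  expect_equal(po$counts[, "extract"], c(a = 22L, b = 38L))
  # anti-correlated replicates trigger the consistency warning
  m2 <- matrix(c(1L, 100L, 100L, 1L), nrow = 2,
               dimnames = list(c("a", "b"), c("e_rep1", "e_rep2")))
  cm2 <- count_matrix(m2, data.frame(
    sample_id = colnames(m2), fraction = "extract", replicate = 1:2,
    stringsAsFactors = FALSE))
  expect_warning(pool_replicates(cm2), "Spearman")
})
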