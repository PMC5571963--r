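# Independent oracles and small fixture builders used across the suite.
# Each oracle is a from-scratch restatement of the quantity it checks,
# kept free of the package code paths it validates.

# --- hypergeometric upper tail by exhaustive subset enumeration --------
# P(X >= k) where X = class members among K draws without replacement
# from N items of which n are class members.
hyper_enum_p <- function(k, N, n, K) {
  if (K == 0) return(as.numeric(k <= 0))
  sets <- utils::combn(N, K)
  hits <- apply(sets, 2, function(s) sum(s <= n))
  mean(hits >= k)
}

# --- Mann-Whitney two-sided p by full permutation enumeration ---------
# No-ties case: U for every assignment of the pooled values to group a;
# two-sided p by symmetry of U around n1*n2/2.
mw_enum_p <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  pool <- c(a, b)
  n1 <- length(a)
  ctr <- n1 * length(b) / 2
  u_obs <- u_stat(a, b)
  sets <- utils::combn(length(pool), n1)
  us <- apply(sets, 2, function(s) u_stat(pool[s], pool[-s]))
  mean(abs(us - ctr) >= abs(u_obs - ctr) - 1e-9)
}

# --- motif scanning: per-window predicates restated from the element
# definitions, plus merging through IRanges::reduce ---------------------
oracle_rule_widths <- list(R1 = 7L, R2 = 7L, R3 = c(6L, 7L), R4 = 7L, R5 = 7L)

oracle_window_hit <- function(win, rule_id) {
  ch <- strsplit(win, "")[[1]]
  nt <- which(ch != "T")
  switch(rule_id,
    R1 = win == "TTCTTTT",
    R2 = win %in% c("GTCTTTT", "GTCTTTG"),
    R3 = win %in% c("GTCTTTT", "GTCTTTA", "TTTTTT"),
    R4 = length(ch) == 7 && length(nt) == 1 && nt >= 2 && nt <= 5 &&
      ch[nt] %in% c("A", "G") && !(nt == 3 && ch[nt] == "G"),
    R5 = length(ch) == 7 && (length(nt) == 0 ||
      (length(nt) == 1 && nt >= 2 && nt <= 6 && ch[nt] %in% c("A", "C", "G") &&
         !(nt == 3 && ch[nt] == "G") && !(nt == 6 && ch[nt] %in% c("A", "G")))),
    stop("unknown rule"))
}

oracle_scan <- function(seq, rule_id) {
  starts <- integer(0); ends <- integer(0)
  for (w in oracle_rule_widths[[rule_id]]) {
    n_win <- nchar(seq) - w + 1L
    if (n_win < 1) next
    for (i in seq_len(n_win)) {
      if (oracle_window_hit(substr(seq, i, i + w - 1L), rule_id)) {
        starts <- c(starts, i); ends <- c(ends, i + w - 1L)
      }
    }
  }
  if (!length(starts)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # min.gapwidth = 0: merge overlapping windows only, never merely
  # adjacent ones (two abutting elements stay two sites)
  merged <- IRanges::reduce(IRanges::IRanges(starts, ends), min.gapwidth = 0L)
  data.frame(start = BiocGenerics::start(merged), end = BiocGenerics::end(merged))
}

random_seq <- function(len, p_t = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - p_t) / 3, (1 - p_t) / 3, (1 - p_t) / 3, p_t)),
        collapse = "")
}

# --- small simulated datasets -----------------------------------------
# Two-fraction design with a known MPR membrane effect; defaults small
# enough for unit tests.
small_sim <- function(n_mpr = 20, n_cpr = 60, mpr_membrane = 2,
                      library_size = 2e5, n_replicates = 3,
                      dispersion = 0.05, seed = 1L, gene_sd = 0) {
  d <- sim_design(n_mpr = n_mpr, n_cpr = n_cpr, n_other = 4,
                  fractions = c("extract", "membrane"),
                  n_replicates = n_replicates, library_size = library_size,
                  rrna_load = c(extract = 0.5, membrane = 0.5),
                  dispersion = dispersion, seed = seed)
  catal <- build_gene_catalog(d)
  tr <- make_sim_truth(catal, d,
                       class_multipliers = list(MPR = c(membrane = mpr_membrane)),
                       gene_sd = gene_sd)
  counts <- simulate_fraction_counts(catal, d, tr)
  list(design = d, catalog = catal, truth = tr, counts = counts)
}

# Enrichment landscape straight from a simulated dataset.
sim_landscape <- function(sim, fraction = "membrane", min_rpkm = 1) {
  rpkm <- compute_rpkm(pool_replicates(
    filter_feature_classes(sim$counts, sim$catalog)), sim$catalog)
  percentile_rank(enrichment_ratio(rpkm, fraction, "extract",
                                   min_rpkm = min_rpkm,
                                   catalog = sim$catalog))
}

# Hand-built enrichment table (bypasses counts entirely).
toy_enrichment <- function(ratios, classes = NULL, ids = NULL) {
  ids <- ids %||% sprintf("g%03d", seq_along(ratios))
  df <- data.frame(gene_id = ids, ratio = ratios, stringsAsFactors = FALSE)
  if (!is.null(classes)) df$loc_class <- classes
  structure(df, class = c("enrichment_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
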