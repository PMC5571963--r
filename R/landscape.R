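#' Rank genes along an enrichment landscape
#'
#' Sorts genes ascending by enrichment ratio and assigns each the
#' midpoint percentile `100 * (rank - 0.5) / N`. Ties in the ratio are
#' broken by gene id, so the ranking is stable and reproducible.
#'
#' @param enrichment An `enrichment_table` (or data.frame with
#'   `gene_id`, `ratio`, optionally `loc_class`).
#' @return A data.frame of class `landscape`: `gene_id`, `ratio`,
#'   `loc_class` (if present), `rank`, `percentile`, sorted ascending.
#' @export
percentile_rank <- function(enrichment) {
  if (nrow(enrichment) < 2) {
    stop_param("percentile_rank: need at least 2 genes")
  }
  o <- order(enrichment$ratio, enrichment$gene_id)
  out <- enrichment[o, , drop = FALSE]
  n <- nrow(out)
  out$rank <- seq_len(n)
  out$percentile <- 100 * (out$rank - 0.5) / n
  rownames(out) <- NULL
  class(out) <- c("landscape", "data.frame")
  for (a in c("fraction", "reference", "min_rpkm")) {
    attr(out, a) <- attr(enrichment, a)
  }
  out
}

#' Class quota along a ranked landscape (moving window)
#'
#' For windows of `window_width` percentiles stepped by `step` along the
#' ranked landscape, computes the quota of each class: class members in
#' the window divided by genes in the window. Edge windows are truncated
#' at 0 and 100. This is the moving-average "quota per decile" view of
#' how a class (e.g. MPRs) distributes along the enrichment landscape.
#'
#' @param landscape A `landscape` from [percentile_rank()].
#' @param classes Named per-gene class labels; defaults to the
#'   landscape's `loc_class` column.
#' @param window_width Window width in percentiles (default 10).
#' @param step Step between window centers in percentiles (default 1).
#' @return Data frame: `center`, `class`, `quota`, `n_window`.
#' @export
quota_curve <- function(landscape, classes = NULL, window_width = 10,
                        step = 1) {
  if (window_width <= 0 || window_width > 100) {
    stop_param("quota_curve: 'window_width' must be in (0, 100]")
  }
  classes <- classes %||% stats::setNames(landscape$loc_class,
                                          landscape$gene_id)
  cls <- classes[landscape$gene_id]
  if (anyNA(cls)) stop_param("quota_curve: classes must cover all genes")
  centers <- seq(0, 100, by = step)
  lv <- unique(cls)
  out <- list()
  for (ct in centers) {
    lo <- max(0, ct - window_width / 2)
    hi <- min(100, ct + window_width / 2)
    inw <- landscape$percentile >= lo & landscape$percentile <= hi
    nw <- sum(inw)
    if (nw == 0) next
    for (cl in lv) {
      out[[length(out) + 1L]] <- data.frame(
        center = ct, class = cl, quota = sum(inw & cls == cl) / nw,
        n_window = nw, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-decile class member counts
#'
#' Counts class members in each of the ten disjoint deciles of the
#' ranked landscape. The counts of a class sum to the class size — a
#' conservation check on any landscape.
#'
#' @param landscape A `landscape`.
#' @param classes Named class labels (default the `loc_class` column).
#' @return Data frame: `decile` (1-10), one column per class.
#' @export
decile_counts <- function(landscape, classes = NULL) {
  classes <- classes %||% stats::setNames(landscape$loc_class,
                                          landscape$gene_id)
  cls <- classes[landscape$gene_id]
  dec <- pmin(floor(landscape$percentile / 10) + 1L, 10L)
  tab <- table(factor(dec, levels = 1:10), cls)
  out <- data.frame(decile = 1:10)
  for (cl in colnames(tab)) out[[cl]] <- as.integer(tab[, cl])
  out
}

#' Tail overrepresentation of a class (hypergeometric test)
#'
#' Tests whether a class is overrepresented among the `tail_fraction`
#' most (side `"top"`) or least (side `"bottom"`) enriched genes of a
#' landscape. With `N` genes, class size `n`, and tail size
#' `K = round(tail_fraction * N)` (boundary genes included by rank
#' order), the p-value is the exact hypergeometric upper tail
#' `P(X >= k)` computed by summation of point masses.
#'
#' @param landscape A `landscape`.
#' @param class Class label to test.
#' @param tail_fraction Tail size as a fraction of all genes, in (0, 1).
#' @param side `"top"` or `"bottom"`.
#' @param classes Named class labels (default the `loc_class` column).
#' @return List of class `tail_test`: `class`, `side`, `tail_fraction`,
#'   `N`, `K`, `n`, `k`, `p_value`.
#' @export
tail_overrepresentation <- function(landscape, class, tail_fraction = 0.30,
                                    side = c("top", "bottom"),
                                    classes = NULL) {
  side <- match.arg(side)
  if (tail_fraction <= 0 || tail_fraction >= 1) {
    stop_param("tail_overrepresentation: 'tail_fraction' must be in (0, 1)")
  }
  classes <- classes %||% stats::setNames(landscape$loc_class,
                                          landscape$gene_id)
  cls <- classes[landscape$gene_id]
  if (!class %in% cls) {
    stop_param("tail_overrepresentation: class '%s' not present", class)
  }
  N <- nrow(landscape)
  K <- as.integer(round(tail_fraction * N))
  in_tail <- if (side == "top") landscape$rank > N - K else landscape$rank <= K
  n <- sum(cls == class)
  k <- sum(in_tail & cls == class)
  structure(list(class = class, side = side, tail_fraction = tail_fraction,
                 N = N, K = K, n = n, k = k,
                 p_value = hyper_upper_tail(k, N, n, K)),
            class = "tail_test")
}

# Exact hypergeometric upper tail P(X >= k) for X ~ Hyper(N, n, K):
# summation of point masses over the attainable range.
hyper_upper_tail <- function(k, N, n, K) {
  hi <- min(n, K)
  if (k <= max(0, n + K - N)) return(1)
  if (k > hi) return(0)
  sum(stats::dhyper(k:hi, m = n, n = N - n, k = K))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement; input order is
#' preserved. Applied over the set of tail tests performed in one run.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_param("bh_fdr: p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Mann-Whitney U test between two groups of enrichment ratios
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with midrank tie
#' handling. The p-value is exact (by enumeration of the U null
#' distribution) when `n1 * n2 <= 400` and there are no ties, and a
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return List of class `rank_test`: `statistic` (U for `a` vs `b`),
#'   `p_value`, `n1`, `n2`, `method`.
#' @export
mann_whitney_test <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop_param("mann_whitney_test: both groups must be non-empty")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 400
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact,
                       alternative = "two.sided"))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n1 = length(a), n2 = length(b),
                 method = if (exact) "exact" else "normal approximation"),
            class = "rank_test")
}

#' Kolmogorov-Smirnov test between two groups of enrichment ratios
#'
#' Two-sample, two-sided KS test on the enrichment distributions;
#' `D = sup |ECDF_a - ECDF_b|`. The p-value is exact for small samples
#' (`n1 * n2 <= 100`, no ties) and asymptotic otherwise.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return List of class `rank_test`: `statistic` (D), `p_value`, `n1`,
#'   `n2`, `method`.
#' @export
ks_test <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop_param("ks_test: both groups must be non-empty")
  }
  exact <- length(a) * length(b) <= 100 && anyDuplicated(c(a, b)) == 0
  ht <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n1 = length(a), n2 = length(b),
                 method = if (exact) "exact" else "asymptotic"),
            class = "rank_test")
}

#' Per-class landscape summary
#'
#' Median and mean enrichment ratio per class, and the class mean as a
#' percent change from the all-gene mean ratio.
#'
#' @param landscape A `landscape`.
#' @param classes Named class labels (default the `loc_class` column).
#' @return Data frame: `class`, `n`, `median_ratio`, `mean_ratio`,
#'   `pct_change_vs_all`.
#' @export
class_summary <- function(landscape, classes = NULL) {
  classes <- classes %||% stats::setNames(landscape$loc_class,
                                          landscape$gene_id)
  cls <- classes[landscape$gene_id]
  all_mean <- mean(landscape$ratio)
  lv <- unique(cls)
  data.frame(
    class = lv,
    n = vapply(lv, function(c) sum(cls == c), integer(1)),
    median_ratio = vapply(lv, function(c) stats::median(landscape$ratio[cls == c]),
                          numeric(1)),
    mean_ratio = vapply(lv, function(c) mean(landscape$ratio[cls == c]),
                        numeric(1)),
    pct_change_vs_all = vapply(lv, function(c) {
      100 * (mean(landscape$ratio[cls == c]) - all_mean) / all_mean
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Select weak- and strong-binder gene groups from a binding landscape
#'
#' From a pull-down binding landscape (elution versus input enrichment),
#' selects the class members found among the `weak_fraction` least-bound
#' genes of the whole landscape ("weak binders") and an equally sized
#' group of class members taken from the top of the binding-sorted list
#' ("strong binders"). Both groups are then intersected with every gene
#' set in `overlap_sets` (e.g. genes detected in all fractions of all
#' strains).
#'
#' @param binding An `enrichment_table` or `landscape` of binding ratios.
#' @param class Class to select within (e.g. `"MPR"`).
#' @param weak_fraction Bottom tail defining weak binders (default 0.30).
#' @param overlap_sets List of gene-id vectors to intersect with
#'   (default none).
#' @param classes Named class labels (default the `loc_class` column).
#' @return List: `weak`, `strong` (character vectors, disjoint),
#'   `weak_pre`, `strong_pre` (before the overlap intersection).
#' @export
select_binder_groups <- function(binding, class = "MPR", weak_fraction = 0.30,
                                 overlap_sets = list(), classes = NULL) {
  land <- if (inherits(binding, "landscape")) binding else percentile_rank(binding)
  classes <- classes %||% stats::setNames(land$loc_class, land$gene_id)
  cls <- classes[land$gene_id]
  if (!class %in% cls) {
    stop_param("select_binder_groups: class '%s' not in the binding table", class)
  }
  N <- nrow(land)
  K <- as.integer(round(weak_fraction * N))
  weak <- land$gene_id[land$rank <= K & cls == class]
  n_weak <- length(weak)
  if (n_weak == 0) {
    stop_param("select_binder_groups: no '%s' gene in the bottom %.0f%%",
               class, 100 * weak_fraction)
  }
  # equal-sized group from the top of the binding-sorted list
  desc <- land$gene_id[order(-land$rank)]
  strong <- desc[classes[desc] == class][seq_len(n_weak)]
  out <- list(weak_pre = weak, strong_pre = strong, weak = weak,
              strong = strong)
  for (s in overlap_sets) {
    out$weak <- intersect(out$weak, s)
    out$strong <- intersect(out$strong, s)
  }
  out
}
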