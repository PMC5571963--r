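#' Remove non-mRNA features from a count matrix
#'
#' Drops rRNA/tRNA/ncRNA rows so that RPKM normalization is computed
#' over mRNA reads only: ribosome-containing fractions are dominated by
#' ribosomal RNA, and leaving those rows in the denominator would make
#' mRNA RPKMs incomparable across fractions. Per-sample totals used by
#' [compute_rpkm()] are recomputed from the retained rows.
#'
#' @param counts A `count_matrix`.
#' @param catalog Gene catalog covering every row.
#' @param keep Feature classes to retain (default `"mRNA"`).
#' @return A filtered `count_matrix`.
#' @export
filter_feature_classes <- function(counts, catalog, keep = "mRNA") {
  stopifnot(inherits(counts, "count_matrix"))
  validate_catalog(catalog)
  miss <- setdiff(rownames(counts$counts), catalog$gene_id)
  if (length(miss)) {
    stop_param("filter_feature_classes: genes absent from catalog: %s",
               paste(utils::head(miss, 10), collapse = ", "))
  }
  feat <- catalog$feature_class[match(rownames(counts$counts), catalog$gene_id)]
  sel <- feat %in% keep
  if (!any(sel)) {
    warning("filter_feature_classes: no rows retained", call. = FALSE)
  }
  count_matrix(counts$counts[sel, , drop = FALSE], counts$samples)
}

#' Pool replicate libraries per fraction
#'
#' Sums replicate counts within each fraction after checking replicate
#' consistency (pairwise Spearman correlation of counts within a
#' fraction must reach `min_spearman`).
#'
#' @param counts A `count_matrix`.
#' @param min_spearman Minimum pairwise Spearman correlation between
#'   replicates of a fraction (default 0.9); set to `NA` to skip the
#'   check.
#' @return A `count_matrix` with one pooled sample per fraction
#'   (`replicate = 0`).
#' @export
pool_replicates <- function(counts, min_spearman = 0.9) {
  stopifnot(inherits(counts, "count_matrix"))
  fr <- unique(counts$samples$fraction)
  pooled <- matrix(0L, nrow = nrow(counts$counts), ncol = length(fr),
                   dimnames = list(rownames(counts$counts), fr))
  for (f in fr) {
    cols <- which(counts$samples$fraction == f)
    sub <- counts$counts[, cols, drop = FALSE]
    if (!is.na(min_spearman) && length(cols) > 1) {
      rho <- stats::cor(sub, method = "spearman")
      low <- min(rho[upper.tri(rho)])
      if (low < min_spearman) {
        warning(sprintf(
          "pool_replicates: fraction '%s' replicate Spearman %.3f < %.2f",
          f, low, min_spearman), call. = FALSE)
      }
    }
    pooled[, f] <- as.integer(rowSums(sub))
  }
  count_matrix(pooled, data.frame(sample_id = fr, fraction = fr,
                                  replicate = 0L, stringsAsFactors = FALSE))
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM(g, s) = count(g, s) * 1e9 / (cds_length(g) * total(s))`, with
#' `total(s)` summed over the rows present in `counts` — i.e. over the
#' mRNA rows when [filter_feature_classes()] has been applied first.
#'
#' @param counts A `count_matrix` (normally mRNA-filtered).
#' @param catalog Gene catalog providing CDS lengths.
#' @return Gene x sample numeric matrix of RPKM values.
#' @export
compute_rpkm <- function(counts, catalog) {
  stopifnot(inherits(counts, "count_matrix"))
  validate_catalog(catalog)
  len <- catalog$cds_length[match(rownames(counts$counts), catalog$gene_id)]
  if (anyNA(len)) {
    stop_param("compute_rpkm: genes missing from catalog")
  }
  totals <- colSums(counts$counts)
  if (any(totals == 0)) {
    stop_param("compute_rpkm: zero total counts in sample(s): %s",
               paste(colnames(counts$counts)[totals == 0], collapse = ", "))
  }
  sweep(counts$counts * 1e9 / len, 2, totals, "/")
}

#' Fraction-to-reference enrichment ratios
#'
#' For every gene detected (RPKM at or above `min_rpkm`) in both the
#' fraction and the reference sample, returns
#' `ratio = RPKM_fraction / RPKM_reference` — the subcellular
#' enrichment landscape coordinate. Genes failing the detection filter
#' are dropped (never pseudo-counted) and listed in the drop report.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()] (pooled samples:
#'   column names are fraction labels).
#' @param fraction Column to compare.
#' @param reference Reference column (e.g. `"extract"`).
#' @param min_rpkm Detection threshold applied to both columns
#'   (default 1).
#' @param catalog Optional catalog; adds a `loc_class` column.
#' @return An object of class `enrichment_table`: data.frame `gene_id`,
#'   `ratio` (and `loc_class` when a catalog is given), with attributes
#'   `fraction`, `reference`, `min_rpkm` and `dropped` (data.frame of
#'   excluded genes and the side that failed).
#' @export
enrichment_ratio <- function(rpkm, fraction, reference, min_rpkm = 1,
                             catalog = NULL) {
  if (identical(fraction, reference)) {
    stop_param("enrichment_ratio: fraction and reference must differ")
  }
  for (lab in c(fraction, reference)) {
    if (!lab %in% colnames(rpkm)) {
      stop_param("enrichment_ratio: no column '%s' in the RPKM table", lab)
    }
  }
  a <- rpkm[, fraction]
  b <- rpkm[, reference]
  pass <- a >= min_rpkm & b >= min_rpkm
  if (!any(pass)) {
    stop_param("enrichment_ratio: no gene passes min_rpkm = %g in both samples",
               min_rpkm)
  }
  dropped <- data.frame(
    gene_id = rownames(rpkm)[!pass],
    reason = ifelse(a[!pass] < min_rpkm & b[!pass] < min_rpkm, "both",
                    ifelse(a[!pass] < min_rpkm, "fraction", "reference")),
    stringsAsFactors = FALSE)
  out <- data.frame(gene_id = rownames(rpkm)[pass],
                    ratio = a[pass] / b[pass],
                    stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    out$loc_class <- catalog$loc_class[match(out$gene_id, catalog$gene_id)]
  }
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            fraction = fraction, reference = reference,
            min_rpkm = min_rpkm, dropped = dropped)
}

#' Genes detected in every enrichment table
#'
#' Intersection of gene ids across a list of enrichment tables —
#' the shared set of mRNAs followed through all fractions so that the
#' same genes are compared on every landscape.
#'
#' @param tables List of `enrichment_table` objects (at least one).
#' @param catalog Optional catalog for per-class counts of the overlap.
#' @return Character vector of shared gene ids; when a catalog is
#'   given, the per-class counts are attached as attribute
#'   `class_counts`.
#' @export
overlap_gene_set <- function(tables, catalog = NULL) {
  if (!length(tables)) stop_param("overlap_gene_set: need at least one table")
  ids <- Reduce(intersect, lapply(tables, function(t) t$gene_id))
  if (!length(ids)) {
    warning("overlap_gene_set: empty intersection", call. = FALSE)
  }
  if (!is.null(catalog)) {
    cls <- catalog$loc_class[match(ids, catalog$gene_id)]
    attr(ids, "class_counts") <- table(factor(cls, levels = unique(catalog$loc_class)))
  }
  ids
}
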