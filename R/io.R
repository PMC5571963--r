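# File formats: tab-separated, UTF-8, '#'-prefixed comments, mandatory
# header; FASTA via Biostrings; JSON via jsonlite.

#' Read a gene x sample count table (TSV)
#'
#' First column = gene id, remaining columns = integer counts per
#' sample. Requires a matching sample-metadata table.
#'
#' @param counts_path TSV of counts.
#' @param metadata_path TSV with columns `sample_id`, `fraction`,
#'   `replicate`.
#' @return A `count_matrix`.
#' @export
read_counts_tsv <- function(counts_path, metadata_path) {
  tab <- read_tsv_checked(counts_path)
  meta <- read_tsv_checked(metadata_path)
  req <- c("sample_id", "fraction", "replicate")
  if (!all(req %in% names(meta))) {
    stop_param("metadata must have columns %s", paste(req, collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m != round(m))) {
    bad <- which(is.na(m) | m != round(m), arr.ind = TRUE)[1, ]
    stop_param("%s: non-integer count at gene '%s', sample '%s'",
               counts_path, tab[[1]][bad[1]], colnames(m)[bad[2]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1]]
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop_param("metadata does not cover all count columns")
  }
  count_matrix(m, meta[, req])
}

#' Read a gene catalog (TSV)
#'
#' Columns: `gene_id`, `cds_length`, `loc_class`, `feature_class`.
#'
#' @param path TSV path.
#' @return Catalog data.frame.
#' @export
read_catalog_tsv <- function(path) {
  cat <- read_tsv_checked(path)
  validate_catalog(cat)
  cat
}

#' Read coding sequences from FASTA
#'
#' @param path Multi-record FASTA (wrapped or unwrapped).
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_cds_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a qPCR Ct table (CSV or TSV)
#'
#' Columns: `gene_id`, `sample`, `ct`.
#'
#' @param path File path (separator inferred from extension; `.csv`
#'   comma, otherwise tab).
#' @return Data frame of class `qpcr_table`.
#' @export
read_qpcr_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE)
  req <- c("gene_id", "sample", "ct")
  if (!all(req %in% names(tab))) {
    stop_param("%s: qPCR table needs columns %s", path, paste(req, collapse = ", "))
  }
  structure(tab[, req], class = c("qpcr_table", "data.frame"))
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = ""),
    error = function(e) stop_param("%s: parse error: %s", path, conditionMessage(e)))
  if (!ncol(tab)) stop_param("%s: empty table", path)
  tab
}

#' Write a data frame as TSV
#'
#' Stable column order, '#' comment support, floats at 6 significant
#' digits.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comment Optional comment line(s) written with a '#' prefix.
#' @export
write_tsv <- function(df, path, comment = NULL) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated data set to disk
#'
#' Emits the counts TSV (genes x samples), sample metadata TSV, catalog
#' TSV, optional FASTA of motif-planted CDS, and a truth JSON.
#'
#' @param dir Output directory (created if absent).
#' @param counts A `count_matrix`.
#' @param catalog Gene catalog.
#' @param truth A `sim_truth` (serialized to JSON).
#' @param sequences Optional named sequences for FASTA output.
#' @return Invisible named vector of written paths.
#' @export
write_simulated_data <- function(dir, counts, catalog, truth = NULL,
                                 sequences = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             catalog = file.path(dir, "catalog.tsv"))
  cdf <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cdf, paths[["counts"]])
  write_tsv(counts$samples, paths[["samples"]])
  write_tsv(catalog, paths[["catalog"]])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(
      list(baseline = as.list(truth$baseline),
           multipliers = as.data.frame(truth$multipliers)),
      paths[["truth"]], auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(sequences)) {
    paths <- c(paths, fasta = file.path(dir, "cds.fasta"))
    write_cds_fasta(sequences, paths[["fasta"]])
  }
  invisible(paths)
}
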