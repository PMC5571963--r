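#' Read and cross-validate all pipeline inputs
#'
#' Loads the count matrix, sample metadata, gene catalog and (optional)
#' CDS FASTA and qPCR table named by a configuration list, and
#' cross-references identifiers: every count row must be in the catalog,
#' and FASTA records absent from the catalog are dropped with a warning.
#'
#' @param config List with elements `counts`, `metadata`, `catalog` and
#'   optionally `fasta`, `qpcr` (file paths).
#' @return List: `counts` (`count_matrix`), `catalog`, `sequences`
#'   (or `NULL`), `qpcr` (or `NULL`).
#' @export
read_inputs <- function(config) {
  for (f in c("counts", "metadata", "catalog")) {
    if (is.null(config[[f]])) stop_param("read_inputs: config lacks '%s'", f)
  }
  counts <- read_counts_tsv(config$counts, config$metadata)
  catalog <- read_catalog_tsv(config$catalog)
  miss <- setdiff(rownames(counts$counts), catalog$gene_id)
  if (length(miss)) {
    stop_param("read_inputs: count genes absent from catalog: %s",
               paste(utils::head(miss, 10), collapse = ", "))
  }
  sequences <- NULL
  if (!is.null(config$fasta)) {
    sequences <- read_cds_fasta(config$fasta)
    extra <- setdiff(names(sequences), catalog$gene_id)
    if (length(extra)) {
      warning(sprintf("read_inputs: %d FASTA record(s) not in catalog ignored",
                      length(extra)), call. = FALSE)
      sequences <- sequences[setdiff(names(sequences), extra)]
    }
  }
  qpcr <- if (!is.null(config$qpcr)) read_qpcr_table(config$qpcr) else NULL
  list(counts = counts, catalog = catalog, sequences = sequences, qpcr = qpcr)
}

#' Run the fractionation-landscape pipeline
#'
#' Chains the analysis stages: feature filtering, replicate pooling,
#' RPKM, per-fraction enrichment versus the reference, overlap gene
#' set, ranked landscapes with quota curves, tail overrepresentation
#' with BH correction, Mann-Whitney and KS class comparisons, and
#' (when sequences are supplied) motif scanning. Artifacts are written
#' under `out_dir` together with a JSON manifest of inputs, parameters
#' and stages run.
#'
#' @param inputs List from [read_inputs()], or the same shape built in
#'   memory (`counts`, `catalog`, optional `sequences`).
#' @param out_dir Output directory.
#' @param reference Reference fraction label (default `"extract"`).
#' @param fractions Fractions to analyze (default: all non-reference
#'   fractions in the metadata).
#' @param min_rpkm Detection threshold (default 1).
#' @param tail_fraction Tail size for overrepresentation (default 0.30).
#' @param window_width,step Quota-curve window parameters.
#' @param classes Classes to test against each other (default
#'   `c("MPR", "CPR")`).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisible list of results per stage; files under `out_dir`.
#' @export
run_pipeline <- function(inputs, out_dir, reference = "extract",
                         fractions = NULL, min_rpkm = 1,
                         tail_fraction = 0.30, window_width = 10, step = 1,
                         classes = c("MPR", "CPR"), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      stop_param("stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages <<- c(stages, name)
    res
  }
  filtered <- run_stage("filter", filter_feature_classes(inputs$counts, inputs$catalog))
  pooled <- run_stage("pool", pool_replicates(filtered))
  rpkm <- run_stage("rpkm", compute_rpkm(pooled, inputs$catalog))
  fractions <- fractions %||% setdiff(colnames(rpkm), reference)
  enr <- run_stage("enrichment", {
    lapply(stats::setNames(fractions, fractions), function(f) {
      enrichment_ratio(rpkm, f, reference, min_rpkm = min_rpkm,
                       catalog = inputs$catalog)
    })
  })
  shared <- run_stage("overlap", overlap_gene_set(enr, inputs$catalog))
  tests <- list()
  landscapes <- list()
  run_stage("landscape", {
    for (f in fractions) {
      tab <- enr[[f]][enr[[f]]$gene_id %in% shared, , drop = FALSE]
      land <- percentile_rank(tab)
      landscapes[[f]] <- land
      write_tsv(as.data.frame(land),
                file.path(out_dir, sprintf("landscape_%s.tsv", f)),
                comment = sprintf("fraction=%s reference=%s", f, reference))
      write_tsv(quota_curve(land, window_width = window_width, step = step),
                file.path(out_dir, sprintf("quota_%s.tsv", f)))
      a <- land$ratio[land$loc_class == classes[1]]
      b <- land$ratio[land$loc_class == classes[2]]
      tests[[f]] <- list(
        fraction = f,
        tail_top = unclass(tail_overrepresentation(land, classes[1],
                                                   tail_fraction, "top")),
        tail_bottom = unclass(tail_overrepresentation(land, classes[1],
                                                      tail_fraction, "bottom")),
        mann_whitney = unclass(mann_whitney_test(a, b)),
        ks = unclass(ks_test(a, b)),
        class_summary = class_summary(land))
    }
  })
  run_stage("tests", {
    p <- vapply(tests, function(t) t$tail_top$p_value, numeric(1))
    q <- bh_fdr(p)
    for (i in seq_along(tests)) tests[[i]]$tail_top$q_value <- q[[i]]
    jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  })
  motifs <- NULL
  if (!is.null(inputs$sequences)) {
    motifs <- run_stage("motifs", {
      sites <- scan_sequences(inputs$sequences)
      write_tsv(sites_to_bed(sites), file.path(out_dir, "motif_sites.bed"))
      sites
    })
  } else {
    message("run_pipeline: no sequences supplied; motif stage skipped")
  }
  manifest <- list(
    inputs = lapply(inputs, function(x) class(x)[1]),
    parameters = list(reference = reference, fractions = fractions,
                      min_rpkm = min_rpkm, tail_fraction = tail_fraction,
                      window_width = window_width, step = step,
                      classes = classes, seed = seed),
    stages = stages,
    n_genes_shared = length(shared),
    version = as.character(utils::packageVersion("fracseq")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(rpkm = rpkm, enrichment = enr, shared = shared,
                 landscapes = landscapes, tests = tests, motifs = motifs,
                 manifest = manifest))
}
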