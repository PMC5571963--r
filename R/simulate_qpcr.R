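#' Simulate a qPCR panel with known fraction portions
#'
#' Generates threshold-cycle (Ct) values for a set of transcripts across
#' a total-extract sample and a set of subcellular fractions such that
#' the delta-Ct mass-balance calculation recovers the planted portions.
#' The forward model inverted here is: relative concentration
#' `2^(Ct_extract - Ct_fraction)`, and portion
#' `rel_conc x mass_fraction / mass_extract`. With zero Ct noise the
#' round trip is exact; Gaussian Ct noise with standard deviation
#' `ct_sd` can be added.
#'
#' @param portions Gene x fraction matrix of true portions (each entry
#'   the fraction of the transcript's extract amount found in that
#'   fraction). Rows named by gene, columns by fraction; entries in
#'   `(0, 1]` (0 allowed, emitted as `NA` Ct = undetected).
#' @param rna_mass Named vector of RNA yields (micrograms) including
#'   `"extract"` and every fraction column.
#' @param ct_extract Baseline extract Ct per gene; scalar or named
#'   vector (default 20).
#' @param ct_sd Gaussian noise sd on every Ct, in cycles (default 0).
#' @param seed Integer seed for the noise stream.
#' @return A data.frame (`gene_id`, `sample`, `ct`) of class
#'   `qpcr_table`, with `rna_mass` attached as an attribute.
#' @export
simulate_qpcr_panel <- function(portions, rna_mass, ct_extract = 20,
                                ct_sd = 0, seed = 1L) {
  if (!is.matrix(portions) || is.null(rownames(portions)) ||
      is.null(colnames(portions))) {
    stop_param("simulate_qpcr_panel: 'portions' must be a named gene x fraction matrix")
  }
  if (any(portions < 0)) stop_param("simulate_qpcr_panel: portions must be >= 0")
  if (any(rna_mass <= 0)) {
    stop_param("simulate_qpcr_panel: RNA masses must be positive")
  }
  need <- c("extract", colnames(portions))
  miss <- setdiff(need, names(rna_mass))
  if (length(miss)) {
    stop_param("simulate_qpcr_panel: 'rna_mass' missing: %s",
               paste(miss, collapse = ", "))
  }
  genes <- rownames(portions)
  if (length(ct_extract) == 1) {
    ct_extract <- stats::setNames(rep(ct_extract, length(genes)), genes)
  }
  rows <- data.frame(gene_id = genes, sample = "extract",
                     ct = unname(ct_extract[genes]), stringsAsFactors = FALSE)
  for (f in colnames(portions)) {
    # portion = 2^(ctE - ctF) * mass_f / mass_E  =>  ctF = ctE - log2(portion * mass_E / mass_f)
    rel <- portions[, f] * rna_mass[["extract"]] / rna_mass[[f]]
    ctf <- ifelse(rel > 0, ct_extract[genes] - log2(rel), NA_real_)
    rows <- rbind(rows, data.frame(gene_id = genes, sample = f,
                                   ct = unname(ctf), stringsAsFactors = FALSE))
  }
  if (ct_sd > 0) {
    rows$ct <- local_seed(seed, rows$ct + stats::rnorm(nrow(rows), 0, ct_sd))
  }
  structure(rows, class = c("qpcr_table", "data.frame"), rna_mass = rna_mass)
}
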