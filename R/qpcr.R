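#' qPCR relative concentration from threshold cycles
#'
#' Relative concentration of a transcript in a fraction versus the
#' total extract, from threshold cycles (Ct):
#' `2^(Ct_extract - Ct_fraction)`. One cycle of difference corresponds
#' to a two-fold concentration difference under perfect amplification
#' efficiency.
#'
#' @param ct_extract Extract Ct (cycles); vectorized.
#' @param ct_fraction Fraction Ct (cycles); vectorized.
#' @return Relative concentration ratio(s).
#' @export
qpcr_relative_concentration <- function(ct_extract, ct_fraction) {
  if (any(!is.finite(ct_extract)) || any(!is.finite(ct_fraction))) {
    stop_param("qpcr_relative_concentration: Ct values must be finite")
  }
  2^(ct_extract - ct_fraction)
}

#' Portion of a transcript found in a fraction
#'
#' Mass-balance portion: the relative concentration (fraction versus
#' extract) weighted by the RNA yields of the two samples,
#' `portion = rel_conc * mass_fraction / mass_extract`. Over disjoint,
#' exhaustive fractions the portions of a transcript sum to 1. When
#' reference-gene Cts are supplied (endogenous controls such as RnpB or
#' SsrA), the relative concentration is first divided by the reference
#' gene's relative concentration to cancel sample-loading differences.
#'
#' @param rel_conc Relative concentration from
#'   [qpcr_relative_concentration()].
#' @param rna_mass_fraction RNA yield of the fraction (micrograms).
#' @param rna_mass_extract RNA yield of the extract (micrograms).
#' @param ref_rel_conc Optional relative concentration of a reference
#'   gene in the same fraction; when given, `rel_conc` is normalized by
#'   it.
#' @return Portion(s) in `[0, Inf)`.
#' @export
qpcr_fraction_portion <- function(rel_conc, rna_mass_fraction,
                                  rna_mass_extract, ref_rel_conc = NULL) {
  if (any(rna_mass_fraction <= 0) || any(rna_mass_extract <= 0)) {
    stop_param("qpcr_fraction_portion: RNA masses must be positive")
  }
  if (!is.null(ref_rel_conc)) {
    rel_conc <- rel_conc / ref_rel_conc
  }
  rel_conc * rna_mass_fraction / rna_mass_extract
}

#' Recover per-fraction portions from a qPCR table
#'
#' Applies [qpcr_relative_concentration()] and
#' [qpcr_fraction_portion()] to every gene and fraction of a Ct table
#' produced by [simulate_qpcr_panel()] or read from file.
#'
#' @param qpcr A data.frame (`gene_id`, `sample`, `ct`) including an
#'   `"extract"` sample per gene.
#' @param rna_mass Named RNA-mass vector covering `"extract"` and every
#'   fraction (defaults to the `rna_mass` attribute of `qpcr`).
#' @param ref_gene Optional reference gene id for endogenous-control
#'   normalization.
#' @return Gene x fraction matrix of portions (`NA` where the Ct was
#'   missing).
#' @export
qpcr_portions <- function(qpcr, rna_mass = attr(qpcr, "rna_mass"),
                          ref_gene = NULL) {
  if (is.null(rna_mass)) stop_param("qpcr_portions: 'rna_mass' required")
  fr <- setdiff(unique(qpcr$sample), "extract")
  genes <- unique(qpcr$gene_id)
  ctm <- matrix(NA_real_, nrow = length(genes), ncol = length(fr) + 1,
                dimnames = list(genes, c("extract", fr)))
  for (i in seq_len(nrow(qpcr))) {
    ctm[qpcr$gene_id[i], qpcr$sample[i]] <- qpcr$ct[i]
  }
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(fr),
                dimnames = list(genes, fr))
  for (f in fr) {
    ok <- is.finite(ctm[, "extract"]) & is.finite(ctm[, f])
    rel <- 2^(ctm[ok, "extract"] - ctm[ok, f])
    ref <- NULL
    if (!is.null(ref_gene)) {
      ref <- 2^(ctm[ref_gene, "extract"] - ctm[ref_gene, f])
    }
    out[ok, f] <- qpcr_fraction_portion(rel, rna_mass[[f]],
                                        rna_mass[["extract"]], ref)
  }
  out
}

#' Standard-curve quality control for qPCR primers
#'
#' Fits `Ct ~ log10(dilution)` by least squares. Perfect two-fold
#' amplification chemistry gives a slope of `-log2(10) = -3.3219`
#' cycles per decade; primers pass when the slope lies in
#' `[-3.6, -3]` and the fit's R-squared exceeds 0.995.
#'
#' @param dilution_log10 log10 relative template amounts (>= 3 points).
#' @param cts Observed Ct at each dilution.
#' @param slope_range Acceptable slope interval (default `c(-3.6, -3)`).
#' @param min_r2 Minimum R-squared (default 0.995).
#' @return List: `slope`, `intercept`, `r_squared`, `pass`.
#' @export
standard_curve_qc <- function(dilution_log10, cts,
                              slope_range = c(-3.6, -3), min_r2 = 0.995) {
  if (length(dilution_log10) < 3 || length(cts) != length(dilution_log10)) {
    stop_param("standard_curve_qc: need >= 3 matched (dilution, Ct) points")
  }
  fit <- stats::lm(cts ~ dilution_log10)
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((cts - mean(cts))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       pass = slope >= slope_range[1] && slope <= slope_range[2] && r2 > min_r2)
}
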