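Package: fracseq
Title: Subcellular mRNA Distribution Analysis from Fractionation RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of subcellular mRNA localization in bacteria from
    cell-fractionation RNA-seq and qPCR data. Computes RPKM and
    fraction-to-extract enrichment ratios from count tables, ranks genes
    along enrichment landscapes and compares membrane-protein-encoding
    mRNAs against cytoplasmic-protein-encoding mRNAs with decile quota
    curves, hypergeometric tail overrepresentation tests with
    Benjamini-Hochberg correction, and Mann-Whitney and
    Kolmogorov-Smirnov tests. Includes a scanner for U-rich cold-shock
    protein recognition elements in coding sequences, K-means clustering
    of log2 expression ratios with Davies-Bouldin model selection, qPCR
    delta-Ct mass-balance quantification, and a synthetic-data generator
    that emulates triplicate fractionation libraries with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    IRanges
Config/testthat/edition: 3
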