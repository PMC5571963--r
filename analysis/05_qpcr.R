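#!/usr/bin/env Rscript
# Stage 5: qPCR mass balance. Simulates a noise-free delta-Ct panel for
# a handful of transcripts distributed over ribosome-free, 70S and
# pellet fractions, recovers the per-fraction portions from the Cts and
# RNA yields, and checks mass conservation; then repeats with realistic
# Ct noise to show the scale of the resulting uncertainty.

suppressPackageStartupMessages(library(fracseq))
dir.create("results/qpcr", showWarnings = FALSE, recursive = TRUE)

# portions in the ranges reported by small-scale fractionation studies:
# 30-60% ribosome-free, 30-45% with 70S ribosomes, 10-20% in the pellet
set.seed(20170825)
genes <- c("mpr_A", "mpr_B", "cpr_A", "cpr_B")
P <- cbind(`ribosome-free` = runif(4, 0.30, 0.60),
           `70S` = runif(4, 0.30, 0.45))
P <- cbind(P, pellet = 1 - rowSums(P))
rownames(P) <- genes
mass <- c(extract = 50, `ribosome-free` = 10, `70S` = 22, pellet = 9)

panel <- simulate_qpcr_panel(P, mass, ct_sd = 0)
rec <- qpcr_portions(panel)
cat("Noise-free recovery (max |error| =",
    format(max(abs(rec - P)), digits = 3), "):\n")
print(round(rec, 4))
cat("Portion sums:", paste(format(rowSums(rec), digits = 6), collapse = " "), "\n")

panel_n <- simulate_qpcr_panel(P, mass, ct_sd = 0.15, seed = 20170826)
rec_n <- qpcr_portions(panel_n)
cat(sprintf("With Ct noise sd = 0.15 cycles: mean |error| = %.3f.\n",
            mean(abs(rec_n - P))))

write_tsv(data.frame(gene_id = rownames(rec), rec, check.names = FALSE),
          "results/qpcr/portions_recovered.tsv")
write_tsv(panel, "results/qpcr/panel_ct.tsv")

# primer QC example: a perfect-efficiency standard curve passes
qc <- standard_curve_qc(c(0, -1, -2, -3), 18 - log2(10) * c(0, -1, -2, -3))
cat(sprintf("Standard-curve QC: slope %.4f, R^2 %.4f, pass = %s.\n",
            qc$slope, qc$r_squared, qc$pass))
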