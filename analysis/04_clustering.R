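#!/usr/bin/env Rscript
# Stage 4: expression-ratio clustering. Builds the log2 ratio matrix of
# each fraction versus the total extract over genes detected in every
# library, chooses K from the Davies-Bouldin profile, fits K-means
# (k-means++, 20 restarts), and merges any single-gene cluster into its
# nearest neighbour.

suppressPackageStartupMessages(library(fracseq))

inputs <- read_inputs(list(counts = "results/data/counts.tsv",
                           metadata = "results/data/samples.tsv",
                           catalog = "results/data/catalog.tsv"))
dir.create("results/clustering", showWarnings = FALSE, recursive = TRUE)

rpkm <- compute_rpkm(pool_replicates(
  filter_feature_classes(inputs$counts, inputs$catalog)), inputs$catalog)
m <- log2_ratio_matrix(rpkm,
                       conditions = c("ribosome-free", "70S", "membrane"),
                       reference = "extract")
cat(sprintf("%d genes detected in all libraries enter the clustering.\n",
            nrow(m)))

sel <- select_k(m, k_range = 2:8, seed = 20170825)
cat("Davies-Bouldin profile:\n"); print(sel$profile)
cat(sprintf("Chosen K = %d%s.\n", sel$k,
            if (nzchar(sel$note)) paste0(" (", sel$note, ")") else ""))

fit <- kmeans_cluster(m, k = sel$k, seed = 20170825)
fit <- merge_singletons(fit, m)
if (length(fit$merge_log)) cat(fit$merge_log, sep = "\n")
cat(sprintf("Final clustering: K = %d, WCSS = %.1f, DB = %.3f.\n",
            fit$k, fit$wcss, fit$db_index))

write_tsv(data.frame(gene_id = names(fit$labels), cluster = fit$labels,
                     loc_class = inputs$catalog$loc_class[
                       match(names(fit$labels), inputs$catalog$gene_id)]),
          "results/clustering/labels.tsv")
write_tsv(data.frame(cluster = seq_len(fit$k), fit$centroids),
          "results/clustering/centroids.tsv")
write_tsv(sel$profile, "results/clustering/db_profile.tsv")
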