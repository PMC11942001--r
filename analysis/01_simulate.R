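#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study cohort.
#
# Emulates the structure the downstream analysis assumes: 100 regulators
# (TFs and miRNAs) organized into 5 correlated clusters driven by latent
# factors with tissue-specific means, and 500 outcome genes that are linear
# in the cluster medoids (with tissue-specific intercepts, a tissue-switch
# subset whose slopes differ by tissue, and an unexplained pure-noise
# subset producing the bimodal R^2 profile). Writes the cohort and its
# ground truth under results/run/.

library(regulome56)

out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_samples = 500, n_tissues = 4,
                        cluster_sizes = c(10, 15, 20, 25, 30),
                        within_cluster_loading = 0.9,
                        regulator_noise_sd = 0.3,
                        n_genes = 500, frac_unexplained = 0.2,
                        frac_tissue_switch = 0.3, gene_noise_sd = 0.5,
                        tissue_separation = 3, seed = 20260925)

rg <- generate_regulators(cfg)
gn <- generate_transcriptome(rg$matrix, rg$truth, cfg)

write_matrix(rg$matrix, file.path(out, "regulators.tsv"))
write_matrix(gn$matrix, file.path(out, "genes.tsv"))
write.table(data.frame(sample_id = rg$matrix$sample_ids,
                       tissue = rg$matrix$tissue),
            file.path(out, "tissues.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(feature_id = names(rg$truth$cluster_assignment),
                       cluster = rg$truth$cluster_assignment,
                       loading = rg$truth$loadings,
                       class = rg$matrix$feature_class),
            file.path(out, "truth_clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = names(gn$truth$gene_category),
                       category = gn$truth$gene_category),
            file.path(out, "truth_gene_categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d samples, %d regulators (%d clusters), %d genes\n",
            nrow(rg$matrix$values), ncol(rg$matrix$values),
            length(cfg$cluster_sizes), ncol(gn$matrix$values)))
cat("gene categories:\n")
print(table(gn$truth$gene_category))
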