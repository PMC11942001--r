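#!/usr/bin/env Rscript
# Stage 3 — fit the Tissue-Agnostic and Tissue-Aware transcriptome models.
#
# Both models use only the medoid panel from stage 2 as predictors. The
# Tissue-Agnostic model is one OLS fit per gene; the Tissue-Aware model
# adds a per-tissue OLS of the global residuals (shared intercept plus one
# linear correction per tissue). Writes per-gene in-sample R^2 for both.

library(regulome56)

out <- "results/run"
regs <- read_matrix(file.path(out, "regulators.tsv"))
genes <- read_matrix(file.path(out, "genes.tsv"))
tiss <- read_tissues(file.path(out, "tissues.tsv"))
regs$tissue <- unname(tiss[regs$sample_ids])
model <- read_component_model(file.path(out, "components.json"))

X <- em_subset(regs, features = model$medoids)
agnostic <- fit_tissue_agnostic(X, genes)
aware <- fit_tissue_aware(X, genes)

r2a <- r_squared(genes, predict(agnostic, X))
r2w <- r_squared(genes, predict(aware, X, tissue = regs$tissue))

write.table(data.frame(gene = names(r2a),
                       r2_agnostic = as.numeric(r2a),
                       r2_aware = as.numeric(r2w)),
            file.path(out, "r2.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("panel: %d medoids -> %d genes, %d samples\n",
            length(model$medoids), length(r2a), nrow(X$values)))
cat(sprintf("mean R^2: Tissue-Agnostic %.3f, Tissue-Aware %.3f\n",
            mean(r2a), mean(r2w)))
cat(sprintf("per-gene dominance violations (aware < agnostic): %d\n",
            sum(r2w < r2a - 1e-12)))
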