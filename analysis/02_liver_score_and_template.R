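#!/usr/bin/env Rscript
# Stage 2: quantify hepatocyte contamination (PCA + liver score) and select
# the template genes for subtype discovery with the two-step filter:
# (i) upregulated in tumors versus non-malignant liver (log2FC > 0,
# FDR <= 0.05), (ii) high cross-tumor SD (> 0.8) on the one-sample-per-patient
# discovery set.

suppressPackageStartupMessages(library(lmsubtype))

out_dir <- "results"
expr <- read_expression_matrix("results/cohort/expression_log2.tsv")
annot <- read_annotation("results/cohort/annotation.tsv")
sets <- read_gmt("results/cohort/genesets.gmt")

# PCA on the top-1000 SD genes; liver score per sample
pc <- pca_scores(expr, n_top = 1000)
ls <- liver_score(expr, sets$LIVER_ENRICHED)
pc1 <- pc$scores[, 1]
cat(sprintf("PC1 explains %.1f%% of variance; cor(PC1, liver score) = %.2f\n",
            100 * pc$var_fraction[1], cor(pc1, ls[rownames(pc$scores)])))

picks <- select_one_sample_per_patient(annot, seed = 20260102L)
tum <- expression_matrix(em_values(expr)[, picks])
nor <- expression_matrix(
  em_values(expr)[, annot$sample_id[annot$tissue == "normal_liver"]])
sel <- select_template_genes(tum, nor)
cat(sprintf("template selection: %d genes -> %d upregulated -> %d high-SD\n",
            sel$counts["input"], sel$counts["step_i"], sel$counts["step_ii"]))

write.table(data.frame(sample_id = names(ls), liver_score = ls,
                       pc1 = pc1[names(ls)]),
            file.path(out_dir, "liver_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(sel$template_genes, file.path(out_dir, "template_genes.txt"))
writeLines(picks, file.path(out_dir, "discovery_samples.txt"))
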