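#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic CRLM cohort that stands in for the deposited
# expression data, and write the fixture files every later stage reads.
#
# The cohort: 169 patients with resected liver metastases (multi-lesion and
# multi-region sampling included), 19 non-malignant liver samples, five
# planted subtypes at prevalences 18/10/19/30/24%, a hepatocyte-contamination
# gradient, subtype-enriched mutations and subtype-dependent survival.

suppressPackageStartupMessages(library(lmsubtype))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260101L

cfg <- simulation_config(seed = seed)
sim <- simulate_cohort(cfg)

write_expression_matrix(sim$expr, file.path(out_dir, "expression_log2.tsv"))
write_annotation(sim$annot, file.path(out_dir, "annotation.tsv"))
write_gmt(sim$sets, file.path(out_dir, "genesets.gmt"))
truth_tab <- data.frame(sample_id = names(sim$truth$true_subtype),
                        true_subtype = sim$truth$true_subtype,
                        true_alpha = sim$truth$true_alpha[
                          names(sim$truth$true_subtype)])
write.table(truth_tab, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_tumor <- sum(sim$annot$tissue == "tumor")
n_multi <- sum(table(sim$annot$patient_id[sim$annot$tissue == "tumor"]) > 1)
cat(sprintf("cohort: %d tumor samples from %d patients (%d multi-sample), %d normal liver\n",
            n_tumor, cfg$n_patients, n_multi, cfg$n_normal))
cat(sprintf("contamination alpha: median %.2f (IQR %.2f-%.2f)\n",
            median(sim$truth$true_alpha),
            quantile(sim$truth$true_alpha, 0.25),
            quantile(sim$truth$true_alpha, 0.75)))
cat("fixtures written to", out_dir, "\n")
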