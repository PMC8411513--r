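#!/usr/bin/env Rscript
# Stage 4: supervised LMS prediction. RFE random-forest model trained on the
# silhouette-positive discovery samples, applied to every tumor sample
# (multi-lesion and multi-region included); a platform-restricted retrain
# emulating an external series missing 10% of the template; and the LMS1
# mini-classifier with its concordance against the full model.

suppressPackageStartupMessages(library(lmsubtype))

seed <- 20260104L
expr <- read_expression_matrix("results/cohort/expression_log2.tsv")
annot <- read_annotation("results/cohort/annotation.tsv")
template <- readLines("results/template_genes.txt")
disc <- read.delim("results/discovery_labels.tsv")
labels <- setNames(disc$lms, disc$sample_id)
sil <- setNames(disc$silhouette, disc$sample_id)

tum <- expression_matrix(em_values(expr)[, disc$sample_id])
model <- train_lms_model(tum, labels, sil, template, seed = seed)
cat(sprintf("RFE retained %d of %d template genes (CV accuracy %.3f)\n",
            model$best_size, length(template),
            max(model$cv_table$accuracy)))

tumor_ids <- annot$sample_id[annot$tissue == "tumor"]
all_expr <- expression_matrix(em_values(expr)[, tumor_ids])
pred <- predict_subtypes(model, all_expr)
write_subtype_calls(pred$labels, pred$posteriors, "results/lms_calls.tsv")

resub <- concordance_report(labels, pred$labels[names(labels)])
cat(sprintf("training-set agreement: %.1f%% (mean balanced accuracy %.1f%%)\n",
            100 * resub$accuracy,
            100 * mean(resub$per_class[, "balanced_accuracy"], na.rm = TRUE)))

# external-platform emulation: drop 10% of the template, retrain on the
# overlap, and predict the sample-standardized data
set.seed(seed)
avail <- sample(template, round(0.9 * length(template)))
platform_model <- retrain_for_platform(
  standardize_samples(tum), labels, template_genes = template,
  available_genes = avail, silhouettes = sil, seed = seed)
ext_pred <- predict_subtypes(platform_model, standardize_samples(all_expr))
cat(sprintf("platform retrain: %d/%d genes; agreement with full model %.1f%%\n",
            length(intersect(template, avail)), length(template),
            100 * mean(ext_pred$labels == pred$labels)))

# LMS1 mini-classifier
mini <- train_mini_classifier(tum, labels, seed = seed + 1L)
cat(sprintf("mini-classifier: %d genes (q <= 0.05, log2FC >= 1.6)\n",
            length(mini$gene_list)))
mini_pred <- predict_mini(mini, all_expr)
full_bin <- ifelse(pred$labels == "LMS1", "LMS1", "not_LMS1")
mini_rep <- concordance_report(full_bin, mini_pred$labels)
cat(sprintf("mini vs full model (LMS1 vs rest): kappa %.2f, accuracy %.2f\n",
            mini_rep$kappa, mini_rep$accuracy))
write.table(data.frame(sample_id = names(mini_pred$labels),
                       mini_call = mini_pred$labels),
            "results/mini_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
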