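#!/usr/bin/env Rscript
# Stage 5: biological characterization of the subtypes. Subtype-versus-rest
# competitive gene-set tests (correlation-adjusted) on the discovery samples,
# and mutation enrichment per subtype (Fisher exact odds ratios for KRAS in
# LMS1 and TP53 in LMS5).

suppressPackageStartupMessages(library(lmsubtype))

expr <- read_expression_matrix("results/cohort/expression_log2.tsv")
annot <- read_annotation("results/cohort/annotation.tsv")
sets <- read_gmt("results/cohort/genesets.gmt")
disc <- read.delim("results/discovery_labels.tsv")
labels <- setNames(disc$lms, disc$sample_id)

tum <- expression_matrix(em_values(expr)[, disc$sample_id])
profile <- subtype_enrichment_profile(tum, labels[colnames(tum)], sets)
write.table(round(profile, 3), "results/enrichment_profile.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
top_sets <- colnames(profile)[apply(profile, 1, which.max)]
cat("top enriched set per subtype:\n")
print(setNames(top_sets, rownames(profile)))

# mutation enrichment: LMS1 vs rest for KRAS, LMS5 vs rest for TP53
pt <- annot[match(disc$sample_id, annot$sample_id), ]
lms1 <- labels == "LMS1"
lms5 <- labels == "LMS5"
kras_tab <- table(lms1, pt$mut_kras)[c("TRUE", "FALSE"), c("TRUE", "FALSE")]
kras <- contingency_stats(kras_tab, "fisher2x2")
cat(sprintf("KRAS in LMS1 vs rest: OR %.1f (p = %.3g)\n",
            kras$odds_ratio, kras$p))
tp53_tab <- table(lms5, pt$mut_tp53)[c("TRUE", "FALSE"), c("TRUE", "FALSE")]
tp53 <- contingency_stats(tp53_tab, "fisher2x2")
cat(sprintf("TP53 in LMS5 vs rest: OR %.2f (p = %.3g)\n",
            tp53$odds_ratio, tp53$p))

ras_tp53 <- pt$mut_kras & pt$mut_tp53
co_tab <- table(lms1, ras_tp53)[c("TRUE", "FALSE"), c("TRUE", "FALSE")]
co <- contingency_stats(co_tab, "fisher2x2")
cat(sprintf("RAS/TP53 co-mutation in LMS1 vs rest: OR %.1f (p = %.3g)\n",
            co$odds_ratio, co$p))
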