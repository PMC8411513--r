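#!/usr/bin/env Rscript
# Stage 3: de novo subtype discovery. Brunet-KL NMF with consensus clustering
# (30 restarts here; raise n_runs to 100 to match the reference protocol) over
# ranks 2-6 on the exponentially transformed template-gene matrix, rank
# selection by cophenetic correlation and silhouette, and LMS naming from
# signature scores.

suppressPackageStartupMessages(library(lmsubtype))

seed <- 20260103L
expr <- read_expression_matrix("results/cohort/expression_log2.tsv")
sets <- read_gmt("results/cohort/genesets.gmt")
template <- readLines("results/template_genes.txt")
picks <- readLines("results/discovery_samples.txt")

tum <- expression_matrix(em_values(expr)[, picks])
V <- as_linear(expression_matrix(em_values(tum)[template, ]))

consensus <- lapply(2:6, function(K) {
  cc <- consensus_cluster(V, K, n_runs = 30, seed = seed)
  cat(sprintf("K=%d  cophenetic=%.4f  mean silhouette=%.3f\n",
              K, cc$cophenetic, cc$mean_silhouette))
  cc
})
names(consensus) <- 2:6

rk <- select_rank(consensus)
write.table(rk$metrics, "results/rank_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("suggested rank(s):", rk$suggested, "\n")

cc5 <- consensus[["5"]]
naming <- assign_subtype_names(cc5, gsva_scores(tum, sets))
labels <- setNames(naming[as.character(cc5$labels)], names(cc5$labels))
cat("subtype proportions at K=5:\n")
print(round(100 * table(labels) / length(labels)))

em_split <- epithelial_mesenchymal_split(consensus[["2"]], cc5)
cat(sprintf("epithelial/mesenchymal concordance K=2 vs K=5: %.1f%% (kappa %.2f)\n",
            100 * em_split$agreement, em_split$kappa))

write.table(data.frame(sample_id = names(labels), lms = labels,
                       silhouette = cc5$silhouette[names(labels)]),
            "results/discovery_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
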