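#!/usr/bin/env Rscript
# Stage 7: correspondence of the de novo subtypes with the established CMS
# and CRIS frameworks, reconstructed from the published cross-tabulation
# (digit-run transcription validated against the printed marginals) and
# summarized as the headline share percentages.

suppressPackageStartupMessages(library(lmsubtype))

counts <- lms_concordance_counts()
cat("LMS x CMS counts:\n"); print(counts$cms)
cat("LMS x CRIS counts:\n"); print(counts$cris)

cris_chi <- contingency_stats(counts$cris)
cat(sprintf("CRIS association: chi-squared %.1f (df %d, p %.2g)\n",
            cris_chi$statistic, cris_chi$df, cris_chi$p))

shares <- lms_concordance_shares(counts)
cat("headline shares (%):\n")
print(round(shares, 1))
write.table(data.frame(share = names(shares), percent = unname(shares)),
            "results/framework_shares.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
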