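---
title: "Transcriptomic subtyping of colorectal liver metastases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic subtyping of colorectal liver metastases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmsubtype)
```

## The problem

Bulk expression profiles of resected colorectal cancer liver metastases
(CRLMs) mix two signals: the cancer cells and a highly variable amount of
surrounding liver tissue. Subtyping frameworks built on primary tumors (CMS,
CRIS) transfer poorly to this setting, so the pipeline in this package
performs *de novo* subtype discovery directly on metastasis profiles and
then makes the discovered classes portable: a liver-metastasis subtype (LMS)
framework with four epithelial-like classes (LMS1 secretory/MSI-like, LMS2
stem-like, LMS3, LMS4 enterocyte-like) and one mesenchymal class (LMS5),
plus a supervised classifier for independent samples and a 9-gene style
mini-classifier for the clinically relevant LMS1 group.

The stages, each an exported function and a numbered script under
`analysis/`:

1. **Contamination accounting** — PCA on the top-1000 SD genes and a
   sample-wise *liver score* (single-sample enrichment of liver-expressed
   genes) quantify hepatocyte infiltration.
2. **Template selection** — genes upregulated in tumors versus non-malignant
   liver (moderated t, log2FC > 0, BH FDR <= 0.05) and then with high
   cross-tumor SD (> 0.8) on one randomly selected sample per patient.
   Keeping only tumor-upregulated genes removes most of the
   contamination-driven variance before factorization.
3. **Discovery** — Brunet-style non-negative matrix factorization
   (Kullback–Leibler objective, multiplicative updates) of the exponentially
   transformed (linear-scale) template matrix, with consensus clustering
   over random restarts; rank selected by the cophenetic correlation
   coefficient and silhouette width over K = 2..6; clusters named from
   signature scores.
4. **Prediction** — recursive feature elimination over random-forest
   ensembles, trained on silhouette-positive samples; platform-restricted
   retraining plus sample-wise standardization for external data; the
   two-class LMS1 mini-classifier on strongly LMS1-elevated genes.
5. **Characterization** — correlation-adjusted competitive gene-set tests
   per subtype, mutation enrichment, survival models, and intra-patient
   heterogeneity accounting.

## The factorization model

With `V` the linear-scale template matrix (genes x samples, all entries
positive), NMF seeks non-negative `W` (genes x K) and `H` (K x samples)
minimizing the generalized Kullback–Leibler divergence
`D(V || WH) = sum(v log(v/wh) - v + wh)`. The multiplicative updates are the
classical ones; each full iteration cannot increase the objective, which the
test suite verifies against a step-by-step re-evaluation oracle. A run stops
when the sample connectivity matrix (co-membership under the argmax of the
columns of `H`) has been unchanged for 40 consecutive checks performed every
10 iterations, or at 2,000 iterations. Initialization is i.i.d.
Uniform(0, 1) scaled by `mean(V)/K`; per-run seeds are derived
deterministically from the master seed, so a fixed seed reproduces the whole
consensus analysis.

Consensus clustering runs `n_runs` restarts (default 100; the tests and the
acceptance script use 30, which on planted cohorts leaves the recovery
metrics unchanged while keeping runtimes in minutes). The consensus matrix
holds co-clustering frequencies; final labels come from average-linkage
hierarchical clustering of `1 - consensus` cut at K — a restart-stable choice
preferred over the best-divergence run, whose labels depend on a single
random initialization. The cophenetic coefficient correlates consensus
distances with the dendrogram's cophenetic distances; silhouettes are
computed on the consensus distance. Rank selection reports the metric table
and the local maxima of the cophenetic profile — conventionally both the
global maximum (often the coarse epithelial/mesenchymal split at K = 2) and
any local maximum at K >= 4 — and never auto-chooses: the caller confirms.

Numerical choices: `eps = 1e-12` guards logs and divisions; `2^x` input is
strictly positive so the KL objective is finite; multiplying `V` by any
positive constant leaves the hard labels unchanged (verified by test).

## Moderated t and the gene-set tests

Differential expression uses the two-group pooled-variance moderated t: the
prior degrees of freedom `d0` and prior variance `s0^2` are estimated by
moment-matching the scaled-F distribution of the gene-wise variances on the
log scale, with the trigamma function inverted by Newton iteration; the
posterior variance is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and the statistic
has `d0 + d_g` degrees of freedom (capped at the pooled residual df). At
`d0 = 0` it is the ordinary pooled t; at `d0 = Inf` gene ranking collapses
onto fold change; when the log-variance spread is no larger than expected
under equal true variances, `d0` is infinite and the prior variance is the
arithmetic mean of the gene variances. The test suite checks exact agreement
with the reference empirical-Bayes implementation. Benjamini–Hochberg
adjustment is implemented as the step-up closed form, validated exhaustively
against a brute-force oracle for small vectors. Only the simple two-group
contrast is supported — it is the only design the pipeline uses.

The competitive gene-set test compares the mean z-transformed moderated
statistic of a set with the mean over the remaining genes. Co-expressed sets
violate the independence assumption of the naive z-test, so the variance of
the set mean is inflated by `VIF = 1 + (m - 1) * rho`, with `rho` the mean
pairwise correlation of the within-group-centered set genes, floored at
`-1/(m - 1)`. Simulations in the test suite show the unadjusted test
rejecting a correlated null (rho = 0.3) about half the time while the
adjusted test stays near the nominal 5%.

## Single-sample scoring

The single-sample scorer follows the gene-set variation approach: a per-gene
cross-sample relative-expression statistic, a per-sample ranking of genes by
that statistic with ranks symmetrized around zero, and a weighted
Kolmogorov–Smirnov random walk per set (weight exponent tau = 1), scored as
the signed sum of the maximum positive and negative deviations ("mx.diff"),
bounded in [-1, 1]. One numerical choice matters: the Gaussian-kernel CDF
(bandwidth = SD/4) is estimated on the per-gene *rank* scale rather than the
raw expression scale. On the rank scale the scores are exactly invariant to
any strictly increasing per-gene transformation — the property the liver
score relies on when comparing across processing pipelines — whereas a
value-scale kernel is only approximately so; and because every gene shares
the same rank set, the kernel reduces to a single shared lookup, making the
scorer O(p n log n) per sample set. The liver score is this scorer applied to
a 157-gene liver-expressed set. Being cross-sample relative, it measures
contamination *within* a cohort: uniformly contaminated cohorts shift no
one's rank, which is why validation plants a contamination *gradient*.

## The classifier chain

`train_lms_model()` implements recursive feature elimination with the
no-leakage discipline: inside each of 3 x 7 stratified cross-validation
folds, a full-feature random forest ranks genes by impurity importance on
the fold's training part only; nested subset sizes (8, 16, ..., 256, all)
are then evaluated on the held-out part. The size with the best mean
accuracy wins (ties to the smaller size), and the final forest is refit on
all training samples with that many top-ranked genes. Ensembles use 500
trees and the `sqrt(p)` features-per-split default; training is restricted
to samples with positive silhouette in the discovery analysis, so borderline
samples do not anchor the decision boundaries. For external platforms the
model is retrained on the template genes the platform measures (with a
warning below 50% overlap and an error below 10 genes), and data are
sample-standardized (per-sample mean 0, SD 1) before prediction.

The mini-classifier takes the genes most specifically elevated in LMS1
(moderated-t q <= 0.05 and log2FC >= 1.6 versus all other subtypes — nine
genes on the real cohort; on synthetic cohorts the count follows the planted
marker strength and is reported, not assumed) and fits a two-class forest
with the features-per-split parameter tuned by 7-fold cross-validation. At
prediction, one absent signature gene is tolerated: gaps within a merged
cohort are imputed by the gene's cohort median; a gene missing from the
platform entirely (where no cohort median exists) falls back to the stored
training-cohort median. Two or more missing genes are an error.

## Survival and heterogeneity

All survival analyses censor events beyond 60 months first (5-year
endpoints, time origin at treatment initiation). Kaplan–Meier estimates use
the product-limit form with Greenwood variance; group comparisons use
pairwise log-rank tests with BH adjustment within endpoint. Cox models use
the Efron tie approximation, Wald confidence intervals, and a
proportional-hazards check via the scaled Schoenfeld residual trend test.
The LMS1 label-switch sensitivity analysis refits the LMS1-versus-rest model
with patients showing inter-metastatic LMS1 heterogeneity counted first in
the LMS1 group and then in the rest, reporting both hazard ratios.

Heterogeneity accounting distinguishes lesions, regions and resections. The
headline fraction is patient-wise among patients with at least two distinct
lesions from the same hepatic resection; patients whose lesions span only
different resections are excluded from it and listed separately. Per-subtype
fractions condition on the patient having at least one same-resection sample
of that subtype. Dendrogram branch analysis clusters multi-sample patients
(Manhattan distance, Ward-D2 linkage, top-1000 SD genes), cuts five main
branches, and calls a patient *adjacent* exactly when their samples form an
exclusive clade — a formalization of visual adjacency; *same-branch,
non-adjacent* and *split* follow from the branch assignment.

## The synthetic cohort

`simulation_config()` defines the study conditions under which every stage
is exercised. The expression model is a hard-membership factorization
`S = W_true H_true` on the linear scale: each subtype elevates its 100
marker genes 8-fold; the mesenchymal subtype additionally carries a 60-gene
stromal block, and a 60-gene shared epithelial block is elevated in the four
epithelial subtypes — together these plant the dominant
epithelial–mesenchymal axis that the K = 2 factorization should find. A
157-gene liver block is near-zero in tumor signal and high in the liver
profile; background genes are shared between tumor and liver so they pass
neither filter step. Expression is `log2(S + 1)` plus N(0, 0.3) noise, plus
a per-patient random effect (SD 0.2) shared by all of a patient's samples —
without it, a patient's lesions would be exchangeable with any same-subtype
sample and adjacent dendrogram clustering could not occur at realistic
rates. Contamination mixes each sample with the liver profile on the linear
scale, `2^x' = (1 - alpha) 2^x + alpha 2^liver`, with alpha ~ Beta(1, 3) —
a continuum from nearly pure tumor to heavily infiltrated, matching the
observed liver-score spread.

Defaults mirror the resected-CRLM setting: 169 patients, 19 normal-liver
samples, prevalences 18/10/19/30/24% (normalized), lesion counts
1 + Geometric(0.73) truncated at 8 (about a quarter of patients
multi-lesion), 10% of lesions sampled in 2–4 regions, a 0.5 per-lesion
subtype-switch probability (so about half of two-lesion patients are
heterogeneous; with more lesions the patient-wise rate runs somewhat above
0.5), KRAS odds ratio 3.9 and a planted hazard ratio of 2.2 for subtype 1,
TP53 odds ratio 0.2 for the mesenchymal subtype, and a 30% censoring
fraction. Survival is exponential with the subtype-1 hazard multiplier, and
censoring is an independent exponential with its rate calibrated so the
marginal censored fraction equals `censor_rate`; independence keeps the Cox
estimand unbiased and proportional hazards true by construction. The
within-subtype expression variance of real cohorts is not documented
quantitatively anywhere we could anchor it, so `noise_sd = 0.3` (log2 units)
was chosen once as a level at which discovery is challenged but solvable,
and not revisited.

What the generator does **not** emulate: probe-level microarray noise,
batch effects between platforms, copy-number-driven expression,
immune/stromal fractions separate from the hepatocyte mixture, and
overlapping or correlated marker programs between subtypes. Passing the
planted-recovery tests therefore shows the machinery is correct and
well-calibrated, not that real CRLM cohorts separate this cleanly —
on real data the distinctions among LMS2–4 are known to be much weaker.

## Problem sizes and determinism

The test suite and the acceptance script run discovery on a 169-sample
cohort with a ~620-gene planted template at 30 consensus restarts per rank,
classifier training at 3 x 7-fold CV with 500-tree forests, the Cox recovery
at 2,000 patients, and the gene-set calibration at 1,000 replicates of a
200-gene, 20-sample null — sizes at which every stochastic check is stable
across seeds. All randomness flows from explicit seed arguments (forests run
single-threaded with fixed seeds), so identical seeds reproduce identical
results end to end.

## Known limitations

- The published cross-tabulation underlying the framework-concordance
  analysis is shipped as a digit-run transcription; its parser requires the
  printed marginal constraints to identify a unique segmentation and fails
  loudly otherwise.
- The moderated t supports only the unpaired two-group contrast; arbitrary
  design matrices are out of scope.
- CMS and CRIS labels are consumed as annotation columns; the external
  classifiers that produce them are not reimplemented.
- The mini-classifier's cross-platform assessment uses per-batch sample
  standardization rather than empirical-Bayes batch correction.
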