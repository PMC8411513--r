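#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`, capped at 1, returned in the
#' input order. Inputs outside \[0, 1\] are rejected.
#'
#' @param p vector of p-values
#' @return vector of BH-adjusted q-values
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Principal component scores on the most variable genes
#'
#' Genes are ranked by cross-sample SD and the top `n_top` retained; the
#' gene-centered (not gene-scaled) matrix is decomposed. The orientation of
#' each component is fixed by requiring a non-negative loading sum, so scores
#' are reproducible across runs and platforms.
#'
#' @param expr log2 [expression_matrix()] with at least 2 samples
#' @param n_top number of top-SD genes to retain (default 1000)
#' @return list with `scores` (samples x components), `var_fraction`,
#'   `loadings` (genes x components) and `genes` (the genes used)
#' @export
pca_scores <- function(expr, n_top = 1000) {
  stopifnot(is_expression_matrix(expr))
  if (ncol(expr) < 2L) stop("PCA needs at least 2 samples")
  if (n_top > nrow(expr)) stop("n_top exceeds the number of genes")
  X <- em_values(expr)
  sds <- apply(X, 1L, stats::sd)
  if (all(sds == 0)) stop("constant expression matrix: zero variance")
  keep <- order(sds, decreasing = TRUE)[seq_len(n_top)]
  Xs <- X[keep, , drop = FALSE]
  pc <- stats::prcomp(t(Xs), center = TRUE, scale. = FALSE)
  flip <- ifelse(colSums(pc$rotation) < 0, -1, 1)
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  list(scores = scores,
       var_fraction = pc$sdev^2 / sum(pc$sdev^2),
       loadings = loadings,
       genes = rownames(Xs))
}

# Newton inversion of the trigamma function (Smyth's moment estimator needs
# trigamma^{-1}; monotone decreasing on (0, Inf))
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Two-group moderated t-test with empirical Bayes variance shrinkage
#'
#' Pooled-variance two-group comparison per gene, with the gene-wise sample
#' variances shrunk toward a common prior: the prior degrees of freedom `d0`
#' and prior variance `s0^2` are estimated by moment-matching the scaled-F
#' distribution of the sample variances (closed-form estimator via trigamma
#' inversion), and the posterior variance is
#' `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`. The moderated t uses `d0 + d_g`
#' degrees of freedom. With `d0 = 0` this is the ordinary pooled t; with
#' `d0 = Inf` all genes share `s0^2` and ranking reduces to fold-change.
#'
#' @param expr log2 [expression_matrix()]
#' @param group logical per sample (TRUE = group of interest) or two-level
#'   factor; the log2 fold-change is group-of-interest minus reference
#' @param d0 optional prior df override (0, finite, or Inf); default estimated
#' @param s02 optional prior variance override
#' @return data.frame of class `DEResult`: per gene `log2fc`, `mean_expr`,
#'   `t_ordinary`, `t_moderated`, `p`, `q`, `df_residual`, `df_prior`,
#'   `s2_prior`, `s2_post`
#' @export
moderated_t_test <- function(expr, group, d0 = NULL, s02 = NULL) {
  stopifnot(is_expression_matrix(expr))
  g <- as_two_groups(group, ncol(expr))
  n1 <- sum(g)
  n2 <- sum(!g)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  d_g <- n1 + n2 - 2L
  if (d_g < 1L) stop("need positive residual degrees of freedom")
  X <- em_values(expr)
  m1 <- rowMeans(X[, g, drop = FALSE])
  m2 <- rowMeans(X[, !g, drop = FALSE])
  v1 <- if (n1 > 1L) apply(X[, g, drop = FALSE], 1L, stats::var) else 0
  v2 <- if (n2 > 1L) apply(X[, !g, drop = FALSE], 1L, stats::var) else 0
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d_g
  if (any(s2 <= 0)) {
    warning(sum(s2 <= 0), " gene(s) with zero pooled variance; set to machine epsilon")
    s2[s2 <= 0] <- .Machine$double.eps
  }
  fc <- m1 - m2
  scale2 <- 1 / n1 + 1 / n2
  t_ord <- fc / sqrt(s2 * scale2)

  # empirical Bayes prior via log-variance moments
  e <- log(s2) - digamma(d_g / 2) + log(d_g / 2)
  emean <- mean(e)
  if (is.null(d0)) {
    evar <- stats::var(e) - trigamma(d_g / 2)
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(evar)
    }
  }
  if (is.null(s02)) {
    s02 <- if (is.infinite(d0)) mean(s2) # no excess log-variance spread
           else if (d0 == 0) NA_real_ # no shrinkage: prior carries no weight
           else exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d_g * s2) / (d0 + d_g)
  t_mod <- fc / sqrt(s2_post * scale2)
  # total df capped at the pooled residual df, the usual moderated-t bound
  df_total <- min(d0 + d_g, length(s2) * d_g)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(gene = rownames(X), log2fc = fc,
                    mean_expr = rowMeans(X), t_ordinary = t_ord,
                    t_moderated = t_mod, p = p, q = bh_adjust(p),
                    df_residual = d_g, df_prior = d0, s2_prior = s02,
                    s2_post = s2_post, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("DEResult", "data.frame")
  res
}

as_two_groups <- function(group, n) {
  if (is.logical(group)) {
    if (length(group) != n) stop("group length must match sample count")
    return(group)
  }
  f <- factor(group)
  if (nlevels(f) != 2L) stop("group must have exactly two levels")
  if (length(f) != n) stop("group length must match sample count")
  f == levels(f)[2L]
}

#' Two-step template-gene selection
#'
#' Step (i) keeps genes upregulated in the tumors relative to the non-malignant
#' liver samples (`log2fc > fc_min` and BH q <= `fdr_max` from an unpaired
#' moderated t-test); step (ii) keeps, among those, the genes with the largest
#' expression variation across the tumor samples (`SD > sd_min`). Restricting
#' to tumor-upregulated genes suppresses the influence of hepatocyte
#' contamination on the downstream factorization.
#'
#' @param expr_tumor log2 tumor [expression_matrix()] (discovery samples)
#' @param expr_normal log2 non-malignant liver matrix over the same genes
#' @param fc_min log2 fold-change threshold (default 0)
#' @param fdr_max FDR threshold (default 0.05)
#' @param sd_min cross-tumor SD threshold (default 0.8)
#' @return list of class `TemplateSelection`: `upregulated_genes`,
#'   `template_genes`, `thresholds`, `counts`, `de` (the full `DEResult`)
#' @export
select_template_genes <- function(expr_tumor, expr_normal, fc_min = 0,
                                  fdr_max = 0.05, sd_min = 0.8) {
  stopifnot(is_expression_matrix(expr_tumor), is_expression_matrix(expr_normal))
  shared <- intersect(rownames(expr_tumor), rownames(expr_normal))
  if (!length(shared)) stop("tumor and normal matrices share no genes")
  Xt <- em_values(expr_tumor)[shared, , drop = FALSE]
  Xn <- em_values(expr_normal)[shared, , drop = FALSE]
  combined <- expression_matrix(cbind(Xt, Xn))
  grp <- c(rep(TRUE, ncol(Xt)), rep(FALSE, ncol(Xn)))
  de <- moderated_t_test(combined, grp)
  up <- de$gene[de$log2fc > fc_min & de$q <= fdr_max]
  if (!length(up)) stop("no genes pass step i (upregulation + FDR filter)")
  sds <- apply(Xt[up, , drop = FALSE], 1L, stats::sd)
  template <- up[sds > sd_min]
  if (!length(template)) stop("no genes pass step ii (SD filter)")
  structure(list(upregulated_genes = up, template_genes = template,
                 thresholds = c(fc_min = fc_min, fdr_max = fdr_max,
                                sd_min = sd_min),
                 counts = c(input = length(shared), step_i = length(up),
                            step_ii = length(template)),
                 de = de),
            class = "TemplateSelection")
}

#' Sample-wise liver score
#'
#' Single-sample enrichment score of a liver-expressed gene set, used as a
#' proxy for hepatocyte contamination of bulk metastasis samples. Delegates to
#' [gsva_scores()]; scores lie in \[-1, 1\].
#'
#' @param expr log2 [expression_matrix()] with at least 3 samples
#' @param liver_set character vector of liver-enriched gene symbols
#' @return named numeric vector, one score per sample
#' @export
liver_score <- function(expr, liver_set) {
  missing_g <- setdiff(toupper(liver_set), toupper(rownames(expr)))
  if (length(missing_g) == length(liver_set))
    stop("no liver genes present in the matrix; missing: ",
         paste(utils::head(missing_g, 10L), collapse = ", "),
         if (length(missing_g) > 10L) ", ...")
  sets <- gene_set_collection(list(LIVER = liver_set))
  gsva_scores(expr, sets)[, "LIVER"]
}

#' Sample-wise centering and scaling
#'
#' Each sample column is centered by its mean over genes and scaled by its SD
#' over genes — the standardization applied before cross-platform prediction.
#'
#' @param expr [expression_matrix()]
#' @return standardized `ExpressionMatrix` (same scale flag)
#' @export
standardize_samples <- function(expr) {
  stopifnot(is_expression_matrix(expr))
  X <- em_values(expr)
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  if (any(sdev == 0))
    stop("zero-SD sample(s): ",
         paste(colnames(X)[sdev == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2L, mu, `-`), 2L, sdev, `/`)
  expression_matrix(Xs, scale_flag = em_scale(expr))
}

#' Select one tumor sample per patient
#'
#' Chooses exactly one tumor sample per patient uniformly at random, ensuring
#' sample independence for subtype discovery; deterministic under a fixed seed.
#'
#' @param annot `CohortAnnotation`
#' @param seed integer seed
#' @param patients optional patient subset; members without a tumor sample are
#'   skipped with a warning
#' @return character vector of selected sample IDs (named by patient)
#' @export
select_one_sample_per_patient <- function(annot, seed, patients = NULL) {
  tumor <- annot[annot$tissue == "tumor", , drop = FALSE]
  if (is.null(patients)) {
    patients <- sort(unique(tumor$patient_id))
  } else {
    no_tumor <- setdiff(patients, tumor$patient_id)
    if (length(no_tumor)) {
      warning("patient(s) without tumor samples skipped: ",
              paste(no_tumor, collapse = ", "))
      patients <- setdiff(patients, no_tumor)
    }
    patients <- sort(patients)
  }
  set.seed(seed)
  picks <- vapply(patients, function(p) {
    ids <- tumor$sample_id[tumor$patient_id == p]
    ids[sample.int(length(ids), 1L)]
  }, character(1L))
  stats::setNames(picks, patients)
}
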