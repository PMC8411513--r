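#' Single-sample gene-set variation scores
#'
#' Per gene, expression values are rank-normalized across samples and a
#' Gaussian-kernel cumulative density estimated on the rank scale
#' (bandwidth = SD of the ranks / 4) gives the cross-sample
#' relative-expression statistic; operating on the rank scale makes the
#' scores exactly invariant to any strictly increasing per-gene
#' transformation of the expression values. Per sample, genes are ranked by
#' that statistic and converted to ranks symmetric around zero; a weighted
#' Kolmogorov-Smirnov random walk (weight exponent `tau`) is run down the
#' ranked list for each set, and the score is the signed sum of the maximum
#' positive and maximum negative deviations (the "mx.diff" convention),
#' which lies in \[-1, 1\].
#'
#' @param expr [expression_matrix()] with at least 3 samples
#' @param sets `GeneSetCollection` (each set must overlap the matrix genes)
#' @param tau rank-weight exponent (default 1)
#' @return samples x sets numeric score matrix (a `SampleScoreTable`)
#' @export
gsva_scores <- function(expr, sets, tau = 1) {
  stopifnot(is_expression_matrix(expr))
  if (ncol(expr) < 3L)
    stop("single-sample scoring needs at least 3 samples")
  X <- em_values(expr)
  genes <- rownames(X)
  set_idx <- lapply(sets, function(g) which(toupper(genes) %in% toupper(g)))
  empty <- names(sets)[lengths(set_idx) == 0L]
  if (length(empty))
    stop("gene set(s) with zero overlap: ", paste(empty, collapse = ", "))

  Z <- kcdf_gaussian(X)
  p <- nrow(X)
  # per sample: rank genes by decreasing z; symmetric rank weight |p/2 - r|
  scores <- matrix(NA_real_, ncol(X), length(sets),
                   dimnames = list(colnames(X), names(sets)))
  for (j in seq_len(ncol(X))) {
    ord <- order(Z[, j], decreasing = TRUE)
    rnk <- integer(p); rnk[ord] <- seq_len(p)
    w <- abs(p / 2 - rnk)^tau
    for (s in seq_along(set_idx)) {
      scores[j, s] <- ks_walk_score(ord, set_idx[[s]], w)
    }
  }
  scores
}

# Gaussian-kernel CDF estimate per gene, computed on within-gene ranks.
# Every gene shares the rank set {1..n} (plus tie averages), so the kernel
# CDF is a single shared lookup; constant genes get a constant statistic.
kcdf_gaussian <- function(X) {
  n <- ncol(X)
  R <- t(apply(X, 1L, rank, ties.method = "average"))
  if (n == 1L) return(matrix(0.5, nrow(X), 1L, dimnames = dimnames(X)))
  h <- stats::sd(seq_len(n)) / 4
  ur <- sort(unique(as.vector(R)))
  zu <- vapply(ur, function(r) mean(stats::pnorm((r - seq_len(n)) / h)),
               numeric(1L))
  Z <- matrix(zu[match(R, ur)], nrow(X), n, dimnames = dimnames(X))
  Z
}

# weighted KS walk: ord = gene indices by decreasing statistic, idx = set
# member indices, w = per-gene rank weights; returns mx.diff score
ks_walk_score <- function(ord, idx, w) {
  p <- length(ord)
  m <- length(idx)
  in_set <- logical(p)
  in_set[idx] <- TRUE
  hits <- in_set[ord]
  wo <- w[ord]
  step_hit <- ifelse(hits, wo, 0)
  denom_hit <- sum(step_hit)
  if (denom_hit == 0) return(0)
  walk <- cumsum(step_hit) / denom_hit - cumsum(!hits) / (p - m)
  max(walk, 0) + min(walk, 0)
}

#' Correlation-adjusted competitive gene-set test
#'
#' For each set, the mean of the set genes' z-transformed moderated
#' t-statistics is compared with the mean over the non-set genes. The
#' inter-gene correlation of the set is estimated from the within-group
#' residuals and inflates the variance of the set mean by
#' `VIF = 1 + (m - 1) * rho`, which keeps the competitive test calibrated for
#' co-expressed sets. Two-sided p-values come from the normal approximation;
#' BH adjustment is applied across sets.
#'
#' @param gene_stats `DEResult` from [moderated_t_test()] on `expr`/`group`
#' @param sets `GeneSetCollection`
#' @param expr the log2 [expression_matrix()] behind `gene_stats`
#' @param group the two-group labels behind `gene_stats`
#' @param fixed_rho optional fixed inter-gene correlation (e.g. 0 to recover
#'   the unadjusted z-test); default: estimated per set
#' @return data.frame of class `GeneSetTestResult`: per set `n_genes`,
#'   `direction`, `delta` (mean stat difference), `rho`, `vif`, `z`, `p`, `q`
#' @export
camera_style_test <- function(gene_stats, sets, expr, group, fixed_rho = NULL) {
  stopifnot(inherits(gene_stats, "DEResult"), is_expression_matrix(expr))
  g <- as_two_groups(group, ncol(expr))
  genes <- gene_stats$gene
  df <- gene_stats$df_prior[1L] + gene_stats$df_residual[1L]
  z <- zscore_t(gene_stats$t_moderated, df)
  p_total <- length(z)

  X <- em_values(expr)[genes, , drop = FALSE]
  resid <- X
  resid[, g] <- X[, g, drop = FALSE] - rowMeans(X[, g, drop = FALSE])
  resid[, !g] <- X[, !g, drop = FALSE] - rowMeans(X[, !g, drop = FALSE])

  s2_all <- stats::var(z)
  rows <- lapply(names(sets), function(nm) {
    idx <- which(toupper(genes) %in% toupper(sets[[nm]]))
    m <- length(idx)
    if (m < 2L) {
      warning("set '", nm, "' has fewer than 2 genes after intersection; skipped")
      return(NULL)
    }
    if (m == p_total) {
      # competitive comparison is empty: the set cannot differ from its
      # complement, so the test is null by construction
      return(data.frame(set = nm, n_genes = m, direction = "up", delta = 0,
                        rho = 0, vif = 1, z = 0, p = 1,
                        stringsAsFactors = FALSE))
    }
    delta <- mean(z[idx]) - mean(z[-idx])
    rho <- if (!is.null(fixed_rho)) fixed_rho else {
      cc <- stats::cor(t(resid[idx, , drop = FALSE]))
      mean(cc[upper.tri(cc)], na.rm = TRUE)
    }
    if (is.na(rho)) rho <- 0
    rho <- max(rho, -1 / (m - 1))
    vif <- 1 + (m - 1) * rho
    se <- sqrt(s2_all * (vif / m + 1 / (p_total - m)))
    zstat <- delta / se
    data.frame(set = nm, n_genes = m,
               direction = ifelse(delta >= 0, "up", "down"),
               delta = delta, rho = rho, vif = vif, z = zstat,
               p = 2 * stats::pnorm(-abs(zstat)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable sets")
  res$q <- bh_adjust(res$p)
  rownames(res) <- NULL
  class(res) <- c("GeneSetTestResult", "data.frame")
  res
}

# t -> standard normal deviate via tail-stable quantile mapping
zscore_t <- function(t, df) {
  df <- min(df, 1e6)
  logp <- stats::pt(-abs(t), df = df, log.p = TRUE)
  -sign(t) * stats::qnorm(logp, log.p = TRUE)
}

#' Subtype-versus-rest enrichment profile
#'
#' For each subtype label, runs [moderated_t_test()] of that subtype against
#' all others followed by [camera_style_test()], and assembles the signed
#' `-log10(q)` significance matrix (positive = enriched up in the subtype).
#'
#' @param expr log2 [expression_matrix()]
#' @param labels per-sample subtype labels (aligned with columns)
#' @param sets `GeneSetCollection`
#' @param min_samples subtypes with fewer samples are skipped with a warning
#' @return subtypes x sets matrix of signed `-log10(q)`
#' @export
subtype_enrichment_profile <- function(expr, labels, sets, min_samples = 3L) {
  labels <- as.character(labels)
  if (length(labels) != ncol(expr))
    stop("labels must align with the matrix columns")
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2L) stop("need at least 2 subtypes")
  out <- matrix(NA_real_, length(subtypes), length(sets),
                dimnames = list(subtypes, names(sets)))
  for (st in subtypes) {
    if (sum(labels == st) < min_samples) {
      warning("subtype '", st, "' has fewer than ", min_samples,
              " samples; skipped")
      next
    }
    de <- moderated_t_test(expr, labels == st)
    gs <- camera_style_test(de, sets, expr, labels == st)
    sgn <- ifelse(gs$direction == "up", 1, -1)
    out[st, gs$set] <- sgn * -log10(pmax(gs$q, 1e-300))
  }
  out
}
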