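#' Non-negative matrix factorization with Kullback-Leibler updates
#'
#' Brunet-style multiplicative updates minimizing the generalized KL
#' divergence `D(V || WH) = sum(v * log(v / wh) - v + wh)`:
#' `H <- H * (t(W) (V / WH)) / colSums(W)` and
#' `W <- W * ((V / WH) t(H)) / rowSums(H)`, iterated from a random positive
#' initialization. The stopping rule follows the original consensus-clustering
#' recipe: every `check_every` iterations the sample connectivity matrix
#' (co-membership under the argmax of H columns) is inspected, and the run
#' stops once it has been unchanged for `stall_checks` consecutive checks, or
#' at `max_iter`.
#'
#' @param V non-negative matrix (genes x samples) or linear-scale
#'   [expression_matrix()]; log2 input must be exponentiated by the caller
#' @param K factorization rank, `K < min(dim(V))`
#' @param seed integer seed for the random initialization
#' @param max_iter iteration cap (default 2000)
#' @param check_every connectivity check interval (default 10)
#' @param stall_checks consecutive unchanged checks that stop the run
#'   (default 40)
#' @param track_divergence record the KL objective at every iteration
#'   (default FALSE; always recorded at checks)
#' @return list of class `FactorizationResult`: `W`, `H`, `K`, `divergence`,
#'   `divergence_trace`, `n_iter`, `converged`, `labels` (argmax of H),
#'   `run_seed`
#' @export
nmf_brunet <- function(V, K, seed = 1L, max_iter = 2000L, check_every = 10L,
                       stall_checks = 40L, track_divergence = FALSE) {
  if (is_expression_matrix(V)) {
    if (em_scale(V) != "linear")
      stop("NMF input must be linear scale; use as_linear()")
    V <- em_values(V)
  }
  if (any(V < 0)) stop("NMF input must be non-negative")
  n <- nrow(V); p <- ncol(V)
  if (K >= min(n, p)) stop("rank K must be smaller than both matrix dimensions")
  eps <- 1e-12
  set.seed(seed)
  scale0 <- mean(V) / K
  W <- matrix(stats::runif(n * K), n, K) * scale0
  H <- matrix(stats::runif(K * p), K, p) * scale0
  kl <- function(WH) sum(V * log((V + eps) / (WH + eps)) - V + WH)

  conn_prev <- NULL
  stall <- 0L
  converged <- FALSE
  trace <- if (track_divergence) numeric(max_iter) else numeric(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WH <- W %*% H
    H <- H * (crossprod(W, V / (WH + eps)) / (colSums(W) + eps))
    WH <- W %*% H
    W <- W * (tcrossprod(V / (WH + eps), H) /
              matrix(rowSums(H) + eps, n, K, byrow = TRUE))
    if (track_divergence) trace[it] <- kl(W %*% H)
    if (it %% check_every == 0L) {
      lab <- max.col(t(H), ties.method = "first")
      conn <- outer(lab, lab, `==`)
      if (!is.null(conn_prev) && identical(conn, conn_prev)) {
        stall <- stall + 1L
        if (stall >= stall_checks) { converged <- TRUE; break }
      } else {
        stall <- 0L
      }
      conn_prev <- conn
    }
  }
  WH <- W %*% H
  labels <- max.col(t(H), ties.method = "first")
  names(labels) <- colnames(V)
  structure(list(W = W, H = H, K = K, divergence = kl(WH),
                 divergence_trace = if (track_divergence) trace[seq_len(it)]
                                    else numeric(0),
                 n_iter = it, converged = converged, labels = labels,
                 run_seed = seed),
            class = "FactorizationResult")
}

#' Consensus clustering over NMF restarts
#'
#' Runs `n_runs` independently seeded factorizations at rank `K`; per run,
#' samples are hard-labeled by the argmax over the columns of H. The consensus
#' matrix holds the fraction of runs co-clustering each sample pair. Final
#' labels come from average-linkage hierarchical clustering of
#' `1 - consensus` cut at `K`; the cophenetic coefficient is the Pearson
#' correlation between the consensus distances and the dendrogram's cophenetic
#' distances, and silhouette widths are computed on the consensus distance
#' against the final labels.
#'
#' @param V non-negative matrix or linear [expression_matrix()]
#' @param K rank
#' @param n_runs number of restarts (default 100)
#' @param seed master seed; per-run seeds are derived from it
#' @param ... passed to [nmf_brunet()]
#' @return list of class `ConsensusResult`: `K`, `consensus`, `cophenetic`,
#'   `silhouette` (per sample), `mean_silhouette`, `labels`, `n_runs`,
#'   `hclust`, `best_run` (lowest-divergence `FactorizationResult`)
#' @export
consensus_cluster <- function(V, K, n_runs = 100L, seed = 1L, ...) {
  if (n_runs < 2L) stop("n_runs must be at least 2")
  if (is_expression_matrix(V)) {
    if (em_scale(V) != "linear")
      stop("NMF input must be linear scale; use as_linear()")
    V <- em_values(V)
  }
  p <- ncol(V)
  consensus <- matrix(0, p, p)
  best <- NULL
  run_seeds <- derive_seeds(seed, n_runs)
  for (r in seq_len(n_runs)) {
    fit <- nmf_brunet(V, K, seed = run_seeds[r], ...)
    lab <- fit$labels
    consensus <- consensus + outer(lab, lab, `==`)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(V), colnames(V))
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = K)
  coph <- stats::cor(as.vector(d), as.vector(stats::cophenetic(hc)))
  if (is.na(coph)) coph <- 1 # zero-variance distances: perfectly reproduced
  sil <- cluster_silhouette(labels, d)
  structure(list(K = K, consensus = consensus, cophenetic = coph,
                 silhouette = sil, mean_silhouette = mean(sil),
                 labels = labels, n_runs = n_runs, hclust = hc,
                 best_run = best),
            class = "ConsensusResult")
}

# per-run seeds derived from the master seed, kept within 32-bit range
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 104729L * seq_len(n)) %% 2147483647L
}

# silhouette width per observation on an arbitrary distance; single-cluster
# partitions get width 0 by convention
cluster_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2L)
    return(stats::setNames(rep(0, length(labels)), names(labels)))
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  stats::setNames(sil[, "sil_width"], names(labels))
}

#' Rank-selection metrics over candidate factorization ranks
#'
#' Tabulates the cophenetic coefficient and mean silhouette per rank and
#' reports the local maxima of the cophenetic profile. Mirroring the practice
#' of retaining both a low-rank split and a finer subtype level, the global
#' maximum and any local maximum at `K >= 4` are reported together; no rank is
#' chosen silently — the caller confirms.
#'
#' @param results list of `ConsensusResult` objects (e.g. for K = 2..6)
#' @return list with `metrics` (data.frame of K, cophenetic, mean silhouette),
#'   `global_max` (K), `local_maxima` (K vector), `suggested` (K vector:
#'   global max plus any K >= 4 local maximum), `no_substructure` flag (TRUE
#'   when the profile is maximal at the K = 2 boundary and decreasing)
#' @export
select_rank <- function(results) {
  if (length(results) < 2L) stop("need at least 2 candidate ranks")
  ks <- vapply(results, `[[`, numeric(1L), "K")
  o <- order(ks)
  results <- results[o]; ks <- ks[o]
  coph <- vapply(results, `[[`, numeric(1L), "cophenetic")
  sil <- vapply(results, `[[`, numeric(1L), "mean_silhouette")
  n <- length(ks)
  is_local_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) coph[i] >= coph[i - 1L] else TRUE
    right <- if (i < n) coph[i] >= coph[i + 1L] else TRUE
    left && right
  }, logical(1L))
  local_maxima <- ks[is_local_max]
  global_max <- ks[which.max(coph)]
  suggested <- sort(unique(c(global_max, local_maxima[local_maxima >= 4])))
  no_substructure <- global_max == min(ks) && all(diff(coph) <= 0)
  list(metrics = data.frame(K = ks, cophenetic = coph, mean_silhouette = sil),
       global_max = global_max, local_maxima = local_maxima,
       suggested = suggested, no_substructure = no_substructure)
}

#' Name consensus clusters as LMS subtypes from signature scores
#'
#' Deterministic naming by mean signature score per cluster: the cluster with
#' the highest mean mesenchymal score becomes LMS5; among the rest, the
#' highest secretory/MSI-like mean becomes LMS1; of the remaining clusters the
#' highest stem mean becomes LMS2, then the highest enterocyte mean becomes
#' LMS4, and the leftover cluster is LMS3. Ties are broken by larger cluster
#' size, then by lower cluster index. At K = 2 only the
#' epithelial/mesenchymal naming applies (the higher mesenchymal mean is the
#' mesenchymal cluster).
#'
#' @param result `ConsensusResult` (K = 5 for full naming, K = 2 for the
#'   epithelial/mesenchymal split)
#' @param scores samples x signatures score matrix (e.g. from
#'   [gsva_scores()])
#' @param signatures named mapping from roles (`mesenchymal`,
#'   `secretory_msi`, `stem`, `enterocyte`) to score column names
#' @return named character vector: cluster index -> subtype name
#' @export
assign_subtype_names <- function(result, scores,
                                 signatures = c(mesenchymal = "MESENCHYMAL",
                                                secretory_msi = "SECRETORY_MSI_LIKE",
                                                stem = "STEM",
                                                enterocyte = "ENTEROCYTE")) {
  labels <- result$labels
  samples <- names(labels)
  if (is.null(samples) || !all(samples %in% rownames(scores)))
    stop("scores must cover all clustered samples")
  needed <- if (result$K == 2L) signatures["mesenchymal"] else signatures
  missing_sig <- setdiff(needed, colnames(scores))
  if (length(missing_sig))
    stop("missing required signature score(s): ",
         paste(missing_sig, collapse = ", "))
  clusters <- sort(unique(labels))
  sizes <- table(factor(labels, levels = clusters))
  mean_score <- function(sig) vapply(clusters, function(cl)
    mean(scores[samples[labels == cl], signatures[[sig]]]), numeric(1L))

  # pick the cluster maximizing a score among candidates; ties -> larger
  # cluster, then lower index
  pick <- function(score_vec, candidates) {
    cand <- which(clusters %in% candidates)
    o <- order(-score_vec[cand], -as.integer(sizes[cand]), clusters[cand])
    clusters[cand][o[1L]]
  }
  naming <- stats::setNames(character(length(clusters)), clusters)
  if (result$K == 2L) {
    mes <- pick(mean_score("mesenchymal"), clusters)
    naming[as.character(mes)] <- "mesenchymal"
    naming[naming == ""] <- "epithelial"
    return(naming)
  }
  remaining <- clusters
  mes <- pick(mean_score("mesenchymal"), remaining)
  naming[as.character(mes)] <- "LMS5"
  remaining <- setdiff(remaining, mes)
  s1 <- pick(mean_score("secretory_msi"), remaining)
  naming[as.character(s1)] <- "LMS1"
  remaining <- setdiff(remaining, s1)
  s2 <- pick(mean_score("stem"), remaining)
  naming[as.character(s2)] <- "LMS2"
  remaining <- setdiff(remaining, s2)
  s4 <- pick(mean_score("enterocyte"), remaining)
  naming[as.character(s4)] <- "LMS4"
  remaining <- setdiff(remaining, s4)
  naming[as.character(remaining)] <- "LMS3"
  naming
}

#' Concordance of the epithelial/mesenchymal split across ranks
#'
#' Maps K = 5 labels to epithelial (LMS1-4) versus mesenchymal (LMS5) and
#' compares with the K = 2 partition (oriented to maximize agreement),
#' returning the agreement fraction and Cohen's kappa.
#'
#' @param result_k2 `ConsensusResult` at K = 2
#' @param result_k5 `ConsensusResult` at K = 5
#' @param lms5_cluster cluster index of LMS5 in `result_k5` (e.g. from
#'   [assign_subtype_names()]); defaults to the K = 5 cluster with the
#'   largest overlap with the smaller K = 2 cluster
#' @return list with `agreement`, `kappa`, `table` (2 x 2 cross-tabulation)
#' @export
epithelial_mesenchymal_split <- function(result_k2, result_k5,
                                         lms5_cluster = NULL) {
  s2 <- names(result_k2$labels)
  s5 <- names(result_k5$labels)
  if (!setequal(s2, s5)) stop("the two factorizations cover different samples")
  l2 <- result_k2$labels[s2]
  l5 <- result_k5$labels[s2]
  if (is.null(lms5_cluster)) {
    minor2 <- names(which.min(table(l2)))
    tab <- table(l5[l2 == minor2])
    lms5_cluster <- as.integer(names(which.max(tab)))
  }
  em5 <- ifelse(l5 == lms5_cluster, "mesenchymal", "epithelial")
  # orient the unnamed K=2 clusters to maximize agreement
  map_a <- ifelse(l2 == sort(unique(l2))[1L], "mesenchymal", "epithelial")
  map_b <- ifelse(l2 == sort(unique(l2))[1L], "epithelial", "mesenchymal")
  em2 <- if (mean(map_a == em5) >= mean(map_b == em5)) map_a else map_b
  rep <- concordance_report(factor(em2, c("epithelial", "mesenchymal")),
                            factor(em5, c("epithelial", "mesenchymal")))
  list(agreement = rep$accuracy, kappa = rep$kappa, table = rep$confusion)
}
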