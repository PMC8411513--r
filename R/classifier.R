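#' Train the multi-class subtype prediction model
#'
#' Recursive feature elimination over random-forest ensembles, trained on the
#' silhouette-positive discovery samples. Feature ranking is recomputed
#' inside every resampling split (no information leaks from held-out folds):
#' per fold, a full-feature forest ranks genes by impurity importance, nested
#' candidate subset sizes are evaluated on the held-out fold, and the subset
#' size with the largest repeated-CV accuracy is retained. The final model is
#' refit on all training samples with that many top-ranked genes.
#'
#' @param expr log2 [expression_matrix()] covering the template genes
#' @param labels named subtype labels (at least the training samples)
#' @param silhouettes named per-sample silhouette widths; training uses
#'   samples with silhouette > 0. `NULL` uses every labeled sample.
#' @param template_genes candidate feature genes (must be in `expr`)
#' @param cv_repeats,cv_folds repeated cross-validation scheme (default 3 x 7)
#' @param subset_sizes candidate RFE sizes; default powers-of-two style
#'   `c(8, 16, 32, 64, 128, 256, all)` clipped to the feature count
#' @param num_trees trees per forest (default 500)
#' @param seed integer seed controlling folds and forests
#' @return list of class `SubtypeModel`: `classes`, `selected_genes`,
#'   `importance`, `fit` (final probability forest), `cv_table` (accuracy per
#'   subset size), `best_size`, `cv_spec`, `seed`
#' @export
train_lms_model <- function(expr, labels, silhouettes = NULL, template_genes,
                            cv_repeats = 3L, cv_folds = 7L,
                            subset_sizes = NULL, num_trees = 500L, seed = 1L) {
  stopifnot(is_expression_matrix(expr))
  missing_g <- setdiff(template_genes, rownames(expr))
  if (length(missing_g))
    stop("template genes missing from matrix: ",
         paste(utils::head(missing_g, 5L), collapse = ", "))
  if (is.null(names(labels))) stop("labels must be named by sample")
  train_ids <- names(labels)
  if (!is.null(silhouettes)) {
    train_ids <- intersect(train_ids, names(silhouettes)[silhouettes > 0])
  }
  train_ids <- intersect(train_ids, colnames(expr))
  y_all <- factor(labels)
  y <- factor(labels[train_ids], levels = levels(y_all))
  if (nlevels(y_all) < 2L) stop("need at least 2 classes")
  if (any(table(y) == 0L))
    stop("class(es) absent from the training set: ",
         paste(levels(y)[table(y) == 0L], collapse = ", "))
  Xt <- t(em_values(expr)[template_genes, train_ids, drop = FALSE])
  p <- length(template_genes)
  if (is.null(subset_sizes))
    subset_sizes <- c(8L, 16L, 32L, 64L, 128L, 256L)
  subset_sizes <- sort(unique(c(subset_sizes[subset_sizes < p], p)))

  set.seed(seed)
  acc <- matrix(NA_real_, cv_repeats * cv_folds, length(subset_sizes),
                dimnames = list(NULL, subset_sizes))
  row <- 0L
  for (rep_i in seq_len(cv_repeats)) {
    folds <- stratified_folds(y, cv_folds)
    for (f in seq_len(cv_folds)) {
      row <- row + 1L
      hold <- folds == f
      rank_g <- rank_features(Xt[!hold, , drop = FALSE], y[!hold],
                              num_trees, seed + 1000L * row)
      for (si in seq_along(subset_sizes)) {
        gsub <- rank_g[seq_len(subset_sizes[si])]
        fit <- ranger::ranger(x = Xt[!hold, gsub, drop = FALSE], y = y[!hold],
                              num.trees = num_trees, num.threads = 1L,
                              seed = seed + 1000L * row + si)
        pred <- stats::predict(fit, data = Xt[hold, gsub, drop = FALSE],
                               num.threads = 1L)$predictions
        acc[row, si] <- mean(pred == y[hold])
      }
    }
  }
  mean_acc <- colMeans(acc)
  best_size <- subset_sizes[which.max(mean_acc)] # ties -> smaller size

  rank_full <- rank_features(Xt, y, num_trees, seed + 7L)
  selected <- rank_full[seq_len(best_size)]
  fit <- ranger::ranger(x = Xt[, selected, drop = FALSE], y = y,
                        num.trees = num_trees, probability = TRUE,
                        importance = "impurity", num.threads = 1L,
                        seed = seed + 11L)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  structure(list(classes = levels(y), selected_genes = names(imp),
                 importance = imp, fit = fit,
                 cv_table = data.frame(size = subset_sizes, accuracy = mean_acc),
                 best_size = best_size,
                 cv_spec = c(repeats = cv_repeats, folds = cv_folds),
                 num_trees = num_trees, train_samples = train_ids,
                 seed = seed),
            class = "SubtypeModel")
}

rank_features <- function(X, y, num_trees, seed) {
  fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                        importance = "impurity", num.threads = 1L,
                        seed = seed)
  names(sort(fit$variable.importance, decreasing = TRUE))
}

# class-stratified fold assignment
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Predict subtypes with a trained model
#'
#' @param model `SubtypeModel`
#' @param expr log2 [expression_matrix()] containing all selected genes
#' @return list with `labels` (named argmax calls) and `posteriors`
#'   (samples x classes, rows summing to 1)
#' @export
predict_subtypes <- function(model, expr) {
  stopifnot(inherits(model, "SubtypeModel"), is_expression_matrix(expr))
  missing_g <- setdiff(model$selected_genes, rownames(expr))
  if (length(missing_g))
    stop("model genes missing from matrix: ",
         paste(missing_g, collapse = ", "))
  Xt <- t(em_values(expr)[model$selected_genes, , drop = FALSE])
  post <- stats::predict(model$fit, data = Xt, num.threads = 1L)$predictions
  rownames(post) <- colnames(expr)
  post <- post / rowSums(post)
  labels <- colnames(post)[max.col(post, ties.method = "first")]
  list(labels = stats::setNames(labels, colnames(expr)), posteriors = post)
}

#' Retrain the subtype model on a platform-restricted template
#'
#' External platforms rarely measure the full template; the model is retrained
#' on the genes both in the template and on the target platform. Target data
#' should be sample-standardized ([standardize_samples()]) before prediction,
#' and the same standardization should be applied to the training matrix.
#'
#' @param expr_train log2 training [expression_matrix()]
#' @param labels named training labels
#' @param template_genes the full template
#' @param available_genes genes measured on the target platform
#' @param silhouettes optional silhouette filter, as in [train_lms_model()]
#' @param ... passed to [train_lms_model()]
#' @return `SubtypeModel` restricted to the overlap
#' @export
retrain_for_platform <- function(expr_train, labels, template_genes,
                                 available_genes, silhouettes = NULL, ...) {
  overlap <- intersect(template_genes, available_genes)
  if (length(overlap) < 10L)
    stop("template overlap with the platform is below 10 genes (",
         length(overlap), ")")
  if (length(overlap) < 0.5 * length(template_genes))
    warning(sprintf("template overlap is only %d/%d genes (%.0f%%)",
                    length(overlap), length(template_genes),
                    100 * length(overlap) / length(template_genes)))
  train_lms_model(expr_train, labels, silhouettes = silhouettes,
                  template_genes = overlap, ...)
}

#' Train the two-class LMS1 mini-classifier
#'
#' Candidate genes are those with strongly elevated expression in LMS1
#' relative to all other subtypes (moderated-t `q <= fdr_max` and
#' `log2fc >= fc_min`, defaults 0.05 and 1.6). A two-class probability forest
#' is fit on the candidates, with the features-per-split parameter tuned by
#' 7-fold cross-validated accuracy. Per-gene training medians are stored as
#' the imputation fallback for platforms missing a gene entirely.
#'
#' @param expr_train log2 [expression_matrix()] of the training cohort
#' @param labels named subtype labels; `"LMS1"` versus everything else
#' @param fc_min log2 fold-change threshold (default 1.6)
#' @param fdr_max FDR threshold (default 0.05)
#' @param cv_folds folds for mtry tuning (default 7)
#' @param num_trees trees (default 500)
#' @param seed integer seed
#' @return list of class `MiniClassifier`: `gene_list`, `fit`, `mtry`,
#'   `train_medians`, `cv_accuracy`, `seed`
#' @export
train_mini_classifier <- function(expr_train, labels, fc_min = 1.6,
                                  fdr_max = 0.05, cv_folds = 7L,
                                  num_trees = 500L, seed = 1L) {
  stopifnot(is_expression_matrix(expr_train))
  ids <- intersect(names(labels), colnames(expr_train))
  y <- factor(ifelse(labels[ids] == "LMS1", "LMS1", "not_LMS1"),
              levels = c("LMS1", "not_LMS1"))
  if (any(table(y) == 0L))
    stop("both LMS1 and non-LMS1 samples are required")
  sub <- expression_matrix(em_values(expr_train)[, ids, drop = FALSE],
                           em_scale(expr_train))
  de <- moderated_t_test(sub, y == "LMS1")
  cand <- de$gene[de$q <= fdr_max & de$log2fc >= fc_min]
  if (!length(cand))
    stop("no genes pass q <= ", fdr_max, " and log2FC >= ", fc_min,
         "; consider relaxing the thresholds")
  Xt <- t(em_values(sub)[cand, , drop = FALSE])
  set.seed(seed)
  mtry_grid <- unique(pmax(1L, pmin(length(cand),
    c(1L, floor(sqrt(length(cand))), max(1L, floor(length(cand) / 3))))))
  folds <- stratified_folds(y, cv_folds)
  cv_acc <- vapply(mtry_grid, function(mt) {
    mean(vapply(seq_len(cv_folds), function(f) {
      hold <- folds == f
      fit <- ranger::ranger(x = Xt[!hold, , drop = FALSE], y = y[!hold],
                            num.trees = num_trees, mtry = mt,
                            num.threads = 1L, seed = seed + f)
      mean(stats::predict(fit, data = Xt[hold, , drop = FALSE],
                          num.threads = 1L)$predictions == y[hold])
    }, numeric(1L)))
  }, numeric(1L))
  best_mtry <- mtry_grid[which.max(cv_acc)]
  fit <- ranger::ranger(x = Xt, y = y, num.trees = num_trees,
                        mtry = best_mtry, probability = TRUE,
                        num.threads = 1L, seed = seed + 101L)
  structure(list(gene_list = cand, fit = fit, mtry = best_mtry,
                 train_medians = apply(Xt, 2L, stats::median),
                 cv_accuracy = stats::setNames(cv_acc, mtry_grid),
                 de = de[de$gene %in% cand, ], seed = seed),
            class = "MiniClassifier")
}

#' Predict LMS1 status with the mini-classifier
#'
#' At most one signature gene may be absent from the input matrix; a missing
#' gene is imputed by its median expression across the prediction cohort when
#' present with gaps, or by the stored training-cohort median when the
#' platform lacks the gene entirely. The imputation is reported.
#'
#' @param mini `MiniClassifier`
#' @param expr log2 [expression_matrix()] of the cohort to classify, or a
#'   plain genes x samples matrix that may contain `NA` gaps for a platform
#'   missing one signature gene (e.g. after a cross-platform merge)
#' @return list with `labels` (named `"LMS1"`/`"not_LMS1"` calls),
#'   `posteriors`, and `imputed` (character, possibly empty)
#' @export
predict_mini <- function(mini, expr) {
  stopifnot(inherits(mini, "MiniClassifier"))
  X <- if (is_expression_matrix(expr)) em_values(expr) else as.matrix(expr)
  missing_g <- setdiff(mini$gene_list, rownames(X))
  gap_g <- setdiff(mini$gene_list[vapply(mini$gene_list, function(g)
    g %in% rownames(X) && anyNA(X[g, ]), logical(1L))], missing_g)
  if (length(missing_g) + length(gap_g) >= 2L)
    stop("mini-classifier requires all but one signature gene; missing: ",
         paste(c(missing_g, gap_g), collapse = ", "))
  Xt <- matrix(NA_real_, ncol(X), length(mini$gene_list),
               dimnames = list(colnames(X), mini$gene_list))
  present <- intersect(mini$gene_list, rownames(X))
  Xt[, present] <- t(X[present, , drop = FALSE])
  imputed <- character(0)
  if (length(gap_g)) {
    # cohort-median imputation across the samples that do measure the gene
    med <- stats::median(Xt[, gap_g], na.rm = TRUE)
    Xt[is.na(Xt[, gap_g]), gap_g] <- med
    imputed <- gap_g
    message("imputed gaps in '", gap_g, "' with its cohort median")
  }
  if (length(missing_g)) {
    Xt[, missing_g] <- mini$train_medians[missing_g]
    imputed <- c(imputed, missing_g)
    message("imputed missing gene '", missing_g,
            "' with its stored training-cohort median")
  }
  post <- stats::predict(mini$fit, data = Xt, num.threads = 1L)$predictions
  rownames(post) <- colnames(X)
  labels <- colnames(post)[max.col(post, ties.method = "first")]
  list(labels = stats::setNames(labels, colnames(X)), posteriors = post,
       imputed = imputed)
}

#' Concordance between two labelings
#'
#' Confusion matrix (rows = `labels_a`, treated as reference), per-class
#' sensitivity/specificity and balanced accuracy, overall accuracy, and
#' Cohen's kappa with its asymptotic 95 percent confidence interval.
#'
#' @param labels_a,labels_b factors/character vectors over the same samples
#'   (aligned positionally, or by names when both are named)
#' @return list of class `ConcordanceReport`
#' @export
concordance_report <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    shared <- intersect(names(labels_a), names(labels_b))
    if (!length(shared)) stop("labelings cover disjoint samples")
    labels_a <- labels_a[shared]
    labels_b <- labels_b[shared]
  }
  if (length(labels_a) != length(labels_b))
    stop("labelings must cover the same samples")
  univ <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = univ)
  b <- factor(as.character(labels_b), levels = univ)
  conf <- table(a, b, dnn = c("reference", "comparison"))
  n <- sum(conf)
  po <- sum(diag(conf)) / n
  pe <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  se <- if (pe == 1) 0 else sqrt(po * (1 - po) / (n * (1 - pe)^2))
  per_class <- t(vapply(univ, function(cl) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    c(sensitivity = sens, specificity = spec,
      balanced_accuracy = (sens + spec) / 2)
  }, numeric(3L)))
  structure(list(confusion = conf, per_class = per_class,
                 accuracy = po, kappa = kappa,
                 kappa_ci = c(lower = kappa - 1.96 * se,
                              upper = kappa + 1.96 * se)),
            class = "ConcordanceReport")
}
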