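# compact training fixture: two separable classes among decoy genes
separable_fixture <- function(n_per = 20, n_decoys = 200, seed = 31) {
  set.seed(seed)
  n <- 2 * n_per
  X <- matrix(rnorm((n_decoys + 1) * n), n_decoys + 1, n,
              dimnames = list(c("KEY", sprintf("D%03d", 1:n_decoys)),
                              sprintf("s%03d", 1:n)))
  y <- rep(c("A", "B"), each = n_per)
  X["KEY", y == "A"] <- X["KEY", y == "A"] + 6
  list(expr = expression_matrix(X), labels = setNames(y, colnames(X)))
}

test_that("RFE keeps a perfectly separating gene and reaches CV accuracy 1", {
  fx <- separable_fixture()
  mod <- train_lms_model(fx$expr, fx$labels, silhouettes = NULL,
                         template_genes = rownames(fx$expr),
                         num_trees = 100, seed = 1)
  expect_true("KEY" %in% mod$selected_genes)
  expect_equal(max(mod$cv_table$accuracy), 1)
  expect_true(all(mod$importance >= 0))
})

test_that("training is deterministic under a fixed seed", {
  fx <- separable_fixture(n_per = 12, n_decoys = 60)
  m1 <- train_lms_model(fx$expr, fx$labels, NULL, rownames(fx$expr),
                        num_trees = 50, seed = 4)
  m2 <- train_lms_model(fx$expr, fx$labels, NULL, rownames(fx$expr),
                        num_trees = 50, seed = 4)
  expect_identical(m1$selected_genes, m2$selected_genes)
  expect_identical(m1$importance, m2$importance)
})

test_that("training validates class structure", {
  fx <- separable_fixture(n_per = 10, n_decoys = 30)
  one_class <- setNames(rep("A", length(fx$labels)), names(fx$labels))
  expect_error(train_lms_model(fx$expr, one_class, NULL, rownames(fx$expr)),
               "2 classes")
  sil <- setNames(ifelse(fx$labels == "B", -1, 1), names(fx$labels))
  expect_error(train_lms_model(fx$expr, fx$labels, sil, rownames(fx$expr)),
               "absent")
})

test_that("prediction is deterministic, normalized and permutation-invariant", {
  fx <- separable_fixture(n_per = 12, n_decoys = 60)
  mod <- train_lms_model(fx$expr, fx$labels, NULL, rownames(fx$expr),
                         num_trees = 50, seed = 4)
  X <- em_values(fx$expr)
  Xd <- cbind(X, dup = X[, 1])
  colnames(Xd) <- c(colnames(X), "dup1")
  pred <- predict_subtypes(mod, expression_matrix(Xd))
  expect_lt(max(abs(rowSums(pred$posteriors) - 1)), 1e-9)
  expect_equal(unname(pred$posteriors["dup1", ]),
               unname(pred$posteriors[colnames(X)[1], ]))
  perm <- expression_matrix(Xd[, rev(colnames(Xd))])
  pred_p <- predict_subtypes(mod, perm)
  expect_equal(pred_p$posteriors[rownames(pred$posteriors), ],
               pred$posteriors)
  expect_error(predict_subtypes(mod, expression_matrix(X[-match(
    mod$selected_genes[1], rownames(X)), , drop = FALSE])), "missing")
})

test_that("held-out subtype prediction reaches the planted accuracy", {
  dc <- discovery_cohort()
  cc5 <- dc$consensus[["5"]]
  sc <- gsva_scores(dc$tum, dc$sim$sets)
  naming <- assign_subtype_names(cc5, sc)
  labels <- setNames(naming[as.character(cc5$labels)], names(cc5$labels))
  mod <- memo("lms_model", function()
    train_lms_model(dc$tum, labels, cc5$silhouette, dc$sel$template_genes,
                    seed = 404))
  X <- em_values(dc$sim$expr)
  held <- setdiff(dc$sim$annot$sample_id[dc$sim$annot$tissue == "tumor"],
                  dc$picks)
  pred <- predict_subtypes(mod, expression_matrix(X[, held]))
  truth <- setNames(paste0("LMS", dc$sim$truth$true_subtype[held]), held)
  rep <- concordance_report(truth, pred$labels)
  expect_gte(min(rep$per_class[, "balanced_accuracy"]), 0.95)
  # resubstitution agreement on the training samples
  back <- predict_subtypes(mod, dc$tum)
  expect_gte(mean(back$labels[names(labels)] == labels), 0.95)
})

test_that("platform retraining handles overlap degradation and degenerate cases", {
  fx <- separable_fixture(n_per = 15, n_decoys = 80)
  full <- train_lms_model(fx$expr, fx$labels, NULL, rownames(fx$expr),
                          num_trees = 50, seed = 6)
  same <- retrain_for_platform(fx$expr, fx$labels,
                               template_genes = rownames(fx$expr),
                               available_genes = rownames(fx$expr),
                               num_trees = 50, seed = 6)
  expect_identical(same$selected_genes, full$selected_genes)
  expect_error(retrain_for_platform(fx$expr, fx$labels,
                                    template_genes = rownames(fx$expr),
                                    available_genes = character(0)),
               "below 10")
  expect_warning(
    retrain_for_platform(fx$expr, fx$labels,
                         template_genes = rownames(fx$expr),
                         available_genes = rownames(fx$expr)[1:30],
                         num_trees = 50, seed = 6),
    "overlap")
})

test_that("platform loss of template genes degrades accuracy only mildly", {
  dc <- discovery_cohort()
  cc5 <- dc$consensus[["5"]]
  sc <- gsva_scores(dc$tum, dc$sim$sets)
  naming <- assign_subtype_names(cc5, sc)
  labels <- setNames(naming[as.character(cc5$labels)], names(cc5$labels))
  full <- memo("lms_model", function()
    train_lms_model(dc$tum, labels, cc5$silhouette, dc$sel$template_genes,
                    seed = 404))
  set.seed(17)
  avail <- sample(dc$sel$template_genes,
                  round(0.9 * length(dc$sel$template_genes)))
  reduced <- retrain_for_platform(dc$tum, labels,
                                  template_genes = dc$sel$template_genes,
                                  available_genes = avail,
                                  silhouettes = cc5$silhouette, seed = 404)
  X <- em_values(dc$sim$expr)
  held <- setdiff(dc$sim$annot$sample_id[dc$sim$annot$tissue == "tumor"],
                  dc$picks)
  truth <- setNames(paste0("LMS", dc$sim$truth$true_subtype[held]), held)
  acc_full <- concordance_report(
    truth, predict_subtypes(full, expression_matrix(X[, held]))$labels)$accuracy
  acc_red <- concordance_report(
    truth, predict_subtypes(reduced, expression_matrix(X[, held]))$labels)$accuracy
  expect_gte(acc_red, acc_full - 0.05)
})

test_that("mini-classifier gene selection respects the fold-change boundary", {
  set.seed(23)
  G <- 60; n <- 40
  X <- matrix(rnorm(G * n, 5, 0.3), G, n,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:n)))
  y <- setNames(rep(c("LMS1", "LMS2"), each = n / 2), colnames(X))
  lms1 <- y == "LMS1"
  X["g01", lms1] <- X["g01", lms1] + 5    # passes easily
  X["g02", lms1] <- X["g02", lms1] + 1.59 # just under the boundary
  mini <- train_mini_classifier(expression_matrix(X), y, num_trees = 100,
                                seed = 3)
  expect_true("g01" %in% mini$gene_list)
  expect_false("g02" %in% mini$gene_list)
  expect_true(all(mini$de$log2fc[match(mini$gene_list, mini$de$gene)] >= 1.6))
  # no passing genes -> instructive error
  Xn <- X; Xn["g01", ] <- rnorm(n, 5, 0.3); Xn["g02", ] <- rnorm(n, 5, 0.3)
  expect_error(train_mini_classifier(expression_matrix(Xn), y),
               "relaxing")
})

test_that("mini-classifier imputes a single missing gene and refuses two", {
  dc <- discovery_cohort()
  cc5 <- dc$consensus[["5"]]
  naming <- assign_subtype_names(cc5, gsva_scores(dc$tum, dc$sim$sets))
  labels <- setNames(naming[as.character(cc5$labels)], names(cc5$labels))
  mini <- memo("mini_model", function()
    train_mini_classifier(dc$tum, labels, seed = 505))
  X <- em_values(dc$tum)
  full_call <- predict_mini(mini, dc$tum)
  expect_identical(full_call$imputed, character(0))
  drop1 <- expression_matrix(X[setdiff(rownames(X), mini$gene_list[1]), ])
  expect_message(call1 <- predict_mini(mini, drop1), "imputed")
  expect_equal(call1$imputed, mini$gene_list[1])
  expect_equal(length(call1$labels), ncol(X))
  drop2 <- expression_matrix(X[setdiff(rownames(X), mini$gene_list[1:2]), ])
  expect_error(predict_mini(mini, drop2), "all but one")
})

test_that("mini and full classifiers agree on the LMS1 distinction", {
  dc <- discovery_cohort()
  cc5 <- dc$consensus[["5"]]
  naming <- assign_subtype_names(cc5, gsva_scores(dc$tum, dc$sim$sets))
  labels <- setNames(naming[as.character(cc5$labels)], names(cc5$labels))
  full <- memo("lms_model", function()
    train_lms_model(dc$tum, labels, cc5$silhouette, dc$sel$template_genes,
                    seed = 404))
  mini <- memo("mini_model", function()
    train_mini_classifier(dc$tum, labels, seed = 505))
  allt <- dc$sim$annot$sample_id[dc$sim$annot$tissue == "tumor"]
  X <- expression_matrix(em_values(dc$sim$expr)[, allt])
  full_bin <- ifelse(predict_subtypes(full, X)$labels == "LMS1",
                     "LMS1", "not_LMS1")
  mini_call <- predict_mini(mini, X)$labels
  rep <- concordance_report(full_bin, mini_call)
  expect_gte(rep$kappa, 0.8)
  expect_gte(rep$accuracy, 0.85)
})

test_that("concordance statistics match hand-computed oracles", {
  rep1 <- concordance_report(c("A", "A", "B"), c("A", "A", "B"))
  expect_equal(rep1$kappa, 1)
  expect_equal(rep1$accuracy, 1)
  # balanced two-class derangement: accuracy 0, kappa -1
  a <- rep(c("A", "B"), 10)
  b <- rep(c("B", "A"), 10)
  rep2 <- concordance_report(a, b)
  expect_equal(rep2$accuracy, 0)
  expect_equal(rep2$kappa, -1)
  # 2x2 table (40,10 / 10,40): kappa 0.6 by the hand formula
  a3 <- rep(c("X", "X", "Y", "Y"), c(40, 10, 10, 40))
  b3 <- rep(c("X", "Y", "X", "Y"), c(40, 10, 10, 40))
  rep3 <- concordance_report(a3, b3)
  expect_equal(rep3$kappa, 0.6)
  expect_equal(unname(rep3$per_class[, "balanced_accuracy"]), c(0.8, 0.8))
  # kappa is symmetric and self-kappa is 1
  expect_equal(concordance_report(a3, b3)$kappa,
               concordance_report(b3, a3)$kappa)
  expect_error(concordance_report(c(x = "A"), c(y = "A")), "disjoint")
})
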