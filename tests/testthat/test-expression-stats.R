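test_that("BH adjustment matches closed forms and independent oracles", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1), 1)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # exhaustive brute-force agreement for every length up to 8
  set.seed(9)
  for (m in 1:8) {
    for (rep_i in 1:20) {
      p <- round(runif(m), 3)
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }
})

test_that("PCA scores match a brute-force eigendecomposition oracle", {
  set.seed(2)
  X <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  pc <- pca_scores(expression_matrix(X), n_top = 3)
  # oracle: eigendecomposition of the gene-gene covariance of centered rows
  Xc <- X - rowMeans(X)
  ev <- eigen(stats::cov(t(Xc)), symmetric = TRUE)
  oracle_scores <- t(Xc) %*% ev$vectors
  flip <- ifelse(colSums(ev$vectors) < 0, -1, 1)
  oracle_scores <- sweep(oracle_scores, 2, flip, `*`)
  k <- 2 # rank bounded by min(genes, samples - 1); compare leading components
  expect_lt(max(abs(pc$scores[, 1:k] - oracle_scores[, 1:k])), 1e-10)
  expect_equal(pc$var_fraction[1:k],
               (ev$values / sum(ev$values))[1:k], tolerance = 1e-8)
})

test_that("PCA degenerate and invariance cases behave", {
  # two samples differing in one gene: PC1 explains everything
  X <- matrix(c(1, 1, 1, 1, 1, 3), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  pc <- pca_scores(expression_matrix(X), n_top = 3)
  expect_equal(pc$var_fraction[1], 1)
  # duplicated samples get identical scores
  sim <- small_cohort()
  X2 <- em_values(sim$expr)[, 1:10]
  Xd <- cbind(X2, dup = X2[, 1])
  colnames(Xd) <- c(colnames(X2), "dup1")
  pcd <- pca_scores(expression_matrix(Xd), n_top = 200)
  expect_equal(unname(pcd$scores["dup1", ]),
               unname(pcd$scores[colnames(X2)[1], ]))
  # constant matrix errors
  Xc <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_error(pca_scores(expression_matrix(Xc), n_top = 4), "zero variance")
})

test_that("moderated t interpolates between ordinary t and fold-change ranking", {
  expr <- rand_expr(150, 12, seed = 21)
  grp <- rep(c(TRUE, FALSE), each = 6)
  de0 <- moderated_t_test(expr, grp, d0 = 0)
  expect_lt(max(abs(de0$t_moderated - de0$t_ordinary)), 1e-12)
  deI <- moderated_t_test(expr, grp, d0 = Inf)
  expect_true(all(deI$s2_post == deI$s2_post[1]))
  expect_equal(order(abs(deI$t_moderated)), order(abs(deI$log2fc)))
})

test_that("moderated t agrees with the reference empirical Bayes fit", {
  skip_if_not_installed("limma")
  expr <- rand_expr(300, 11, seed = 33)
  grp <- c(rep(TRUE, 6), rep(FALSE, 5))
  de <- moderated_t_test(expr, grp)
  design <- cbind(1, as.numeric(grp))
  fit <- limma::eBayes(limma::lmFit(em_values(expr), design))
  expect_equal(de$df_prior[1], fit$df.prior, tolerance = 1e-8)
  expect_equal(de$s2_prior[1], fit$s2.prior, tolerance = 1e-8)
  expect_lt(max(abs(de$t_moderated - fit$t[, 2])), 1e-10)
  expect_lt(max(abs(de$p - fit$p.value[, 2])), 1e-10)
  expect_true(all(de$q >= de$p))
})

test_that("moderated t controls the FDR in simulation", {
  # 200 genes, 50 true positives at delta = 2, n = 5 vs 5, sigma = 1
  set.seed(55)
  reps <- 60
  fdrs <- replicate(reps, {
    X <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:10)))
    X[1:50, 1:5] <- X[1:50, 1:5] + 2
    de <- moderated_t_test(expression_matrix(X), rep(c(TRUE, FALSE), each = 5))
    called <- which(de$q <= 0.05)
    if (!length(called)) return(NA_real_)
    mean(called > 50)
  })
  expect_lte(mean(fdrs, na.rm = TRUE), 0.07)
})

test_that("template selection applies both filter steps and recovers planted genes", {
  # boundary behavior on a constructed matrix
  set.seed(8)
  G <- 40
  Xt <- matrix(rnorm(G * 20, 5, 0.05), G, 20,
               dimnames = list(sprintf("g%02d", 1:G), sprintf("t%02d", 1:20)))
  Xn <- matrix(rnorm(G * 10, 5, 0.05), G, 10,
               dimnames = list(sprintf("g%02d", 1:G), sprintf("n%02d", 1:10)))
  Xt["g01", ] <- Xt["g01", ] - 3            # down in tumors, high SD irrelevant
  Xt["g02", ] <- Xt["g02", ] + 2            # up, but tiny SD
  Xt["g03", ] <- rnorm(20, 7, 2)            # up and variable
  sel <- select_template_genes(expression_matrix(Xt), expression_matrix(Xn))
  expect_false("g01" %in% sel$upregulated_genes)
  expect_true("g02" %in% sel$upregulated_genes)
  expect_false("g02" %in% sel$template_genes)
  expect_true("g03" %in% sel$template_genes)
  expect_true(all(sel$template_genes %in% sel$upregulated_genes))

  # monotonicity: raising sd_min never adds genes
  sim <- small_cohort()
  picks <- select_one_sample_per_patient(sim$annot, seed = 2)
  tum <- expression_matrix(em_values(sim$expr)[, picks])
  nor <- expression_matrix(em_values(sim$expr)[
    , sim$annot$sample_id[sim$annot$tissue == "normal_liver"]])
  s_lo <- select_template_genes(tum, nor, sd_min = 0.6)
  s_hi <- select_template_genes(tum, nor, sd_min = 1.0)
  expect_true(all(s_hi$template_genes %in% s_lo$template_genes))

  # planted recovery at default thresholds, at the discovery scale
  dc <- discovery_cohort()
  planted <- c(unlist(dc$sim$truth$marker_map, use.names = FALSE),
               dc$sim$truth$stroma_genes, dc$sim$truth$epithelial_genes)
  expect_gte(mean(planted %in% dc$sel$template_genes), 0.95)
  expect_lte(mean(!(dc$sel$template_genes %in% planted)), 0.05)
})

test_that("sample standardization is definitional and idempotent", {
  expr <- rand_expr(60, 8, seed = 12)
  s1 <- standardize_samples(expr)
  expect_lt(max(abs(colMeans(em_values(s1)))), 1e-12)
  expect_lt(max(abs(apply(em_values(s1), 2, sd) - 1)), 1e-12)
  s2 <- standardize_samples(s1)
  expect_lt(max(abs(em_values(s2) - em_values(s1))), 1e-12)
  # hand-computed 3 x 2 oracle
  X <- matrix(c(1, 2, 6, 3, 5, 10), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  got <- em_values(standardize_samples(expression_matrix(X)))
  expect_equal(got[, 1], (X[, 1] - 3) / sd(X[, 1]))
  expect_equal(got[, 2], (X[, 2] - 6) / sd(X[, 2]))
  # zero-SD sample errors by name
  X[, 2] <- 4
  expect_error(standardize_samples(expression_matrix(X)), "s2")
})

test_that("one-sample-per-patient selection is seeded, uniform and total", {
  annot <- cohort_annotation(data.frame(
    sample_id = c("a1", "a2", "a3", "b1", "n1"),
    patient_id = c("A", "A", "A", "B", "NP"),
    tissue = c("tumor", "tumor", "tumor", "tumor", "normal_liver"),
    stringsAsFactors = FALSE))
  expect_identical(select_one_sample_per_patient(annot, seed = 1),
                   select_one_sample_per_patient(annot, seed = 1))
  expect_equal(unname(select_one_sample_per_patient(annot, seed = 1)["B"]),
               "b1")
  expect_warning(select_one_sample_per_patient(annot, seed = 1,
                                               patients = c("A", "Z")),
                 "Z")
  draws <- vapply(1:3000, function(s)
    select_one_sample_per_patient(annot, seed = s)[["A"]], character(1))
  freq <- table(draws) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("liver score tracks planted contamination monotonically", {
  sim <- small_cohort()
  ls <- liver_score(sim$expr, sim$sets$LIVER_ENRICHED)
  expect_true(all(ls >= -1 & ls <= 1))
  rho <- cor(ls[names(sim$truth$true_alpha)], sim$truth$true_alpha,
             method = "spearman")
  expect_gte(rho, 0.9)

  # a pure liver-profile sample attains the maximum score of a clean cohort
  gen <- generate_expression(simulation_config(
    n_patients = 20, n_normal = 0, n_genes = 500,
    n_template_markers_per_subtype = 15, mesenchymal_extra = 10,
    epithelial_shared = 10, n_liver_genes = 30,
    contamination_alpha = c(1, 1),
    lesions_per_patient = list(prob = 1, max = 1), seed = 77))
  X <- em_values(gen$expr)
  X <- cbind(X, PURE = gen$truth$liver_log2)
  scores <- liver_score(expression_matrix(X), gen$truth$liver_genes)
  expect_equal(names(which.max(scores)), "PURE")

  # graded copies of one sample, placed in a cohort spanning the full
  # contamination continuum, score strictly increasingly in alpha
  ids <- names(gen$truth$true_subtype)
  grid <- c(0, 0.25, 0.5, 0.75)
  cohort <- apply_liver_contamination(gen$expr, gen$truth)
  base <- em_values(gen$expr)
  copies <- sapply(grid, function(a) {
    one <- expression_matrix(base[, ids[1], drop = FALSE])
    em_values(apply_liver_contamination(one, gen$truth,
                                        stats::setNames(a, ids[1])))
  })
  colnames(copies) <- paste0("A", seq_along(grid))
  mixed <- expression_matrix(cbind(em_values(cohort)[, ids[-1]], copies))
  grad <- liver_score(mixed, gen$truth$liver_genes)[colnames(copies)]
  expect_true(all(diff(grad) > 0))
  expect_error(liver_score(sim$expr, c("NOT_A_GENE_1", "NOT_A_GENE_2")),
               "missing")
})
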