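test_that("the KM estimator matches the closed-form product on a toy set", {
  fit <- km_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), rep("g", 4))
  expect_equal(fit$km$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(all(diff(fit$km$surv) <= 0))
})

test_that("log-rank on duplicated groups is exactly null", {
  set.seed(3)
  t1 <- rexp(40, 0.02); e1 <- rbinom(40, 1, 0.7)
  fit <- km_logrank(c(t1, t1), c(e1, e1), rep(c("a", "b"), each = 40))
  expect_equal(unname(fit$overall["chisq"]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$overall["p"]), 1, tolerance = 1e-10)
  expect_equal(fit$pairwise$p, 1, tolerance = 1e-10)
  # invariance: relabeling groups and shifting all times
  fit2 <- km_logrank(c(t1, t1) + 5, c(e1, e1), rep(c("z", "y"), each = 40))
  expect_equal(unname(fit2$overall["chisq"]), unname(fit$overall["chisq"]),
               tolerance = 1e-10)
  expect_error(km_logrank(t1, e1, factor(rep("a", 40), levels = c("a", "b"))),
               "empty")
})

test_that("the log-rank test has power against a planted hazard ratio", {
  set.seed(9)
  rejections <- replicate(60, {
    t1 <- rexp(200, 0.02); t2 <- rexp(200, 0.04)
    cens <- runif(400, 0, 100)
    times <- pmin(c(t1, t2), cens)
    events <- as.numeric(c(t1, t2) <= cens)
    fit <- km_logrank(times, events, rep(c("a", "b"), each = 200))
    fit$overall["p"] < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("events beyond the five-year horizon are censored before testing", {
  fit <- km_logrank(c(10, 70, 80), c(1, 1, 1), rep("g", 3),
                    truncate_months = 60)
  expect_equal(max(fit$km$time), 60)
  expect_equal(sum(fit$km$n.event), 1)
})

test_that("Cox fits recover null effects and flag diagnostics", {
  set.seed(5)
  t1 <- rexp(150, 0.02); e1 <- rbinom(150, 1, 0.8)
  cf <- cox_fit(c(t1, t1), c(e1, e1),
                data.frame(arm = rep(c(0, 1), each = 150)))
  expect_lt(abs(cf$coefficients$beta), 1e-8)
  expect_equal(cf$coefficients$hr, 1, tolerance = 1e-6)
  expect_true(!is.null(cf$ph))
  expect_true(cf$coefficients$ci_lower <= cf$coefficients$hr)
  expect_true(cf$coefficients$ci_upper >= cf$coefficients$hr)
  expect_error(cox_fit(t1, e1, data.frame(const = rep(1, 150))), "constant")
  expect_error(cox_fit(c(5, 6), c(0, 0), data.frame(x = c(0, 1))),
               "fewer events")
})

test_that("bivariable Cox recovers independently planted effects", {
  set.seed(11)
  n <- 2000
  x1 <- rbinom(n, 1, 0.3)
  x2 <- rbinom(n, 1, 0.4)
  rate <- 0.017 * exp(log(2.2) * x1 + log(1.6) * x2)
  times <- rexp(n, rate)
  cens <- rexp(n, 0.007)
  cf <- cox_fit(pmin(times, cens), as.numeric(times <= cens),
                data.frame(lms1 = x1, comut = x2), truncate_months = Inf)
  expect_true(cf$coefficients$ci_lower[1] <= 2.2 &&
              2.2 <= cf$coefficients$ci_upper[1])
  expect_true(cf$coefficients$ci_lower[2] <= 1.6 &&
              1.6 <= cf$coefficients$ci_upper[2])
})

test_that("chi-squared and Fisher statistics match enumeration oracles", {
  even <- matrix(c(10, 10, 10, 10), 2)
  cs <- contingency_stats(even)
  expect_equal(cs$statistic, 0)
  ft <- contingency_stats(even, "fisher2x2")
  expect_equal(ft$odds_ratio, 1, tolerance = 1e-6)

  tab <- matrix(c(12, 3, 5, 20), 2) # rows: (12,5 / 3,20)
  # brute-force chi-squared
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(contingency_stats(tab)$statistic, sum((tab - E)^2 / E))
  # Fisher p by exhaustive hypergeometric enumeration
  ftab <- contingency_stats(tab, "fisher2x2")
  k_obs <- tab[1, 1]
  m1 <- rowSums(tab)[1]; m2 <- rowSums(tab)[2]; c1 <- colSums(tab)[1]
  support <- max(0, c1 - m2):min(c1, m1)
  probs <- dhyper(support, m1, m2, c1)
  p_oracle <- sum(probs[probs <= dhyper(k_obs, m1, m2, c1) * (1 + 1e-7)])
  expect_equal(ftab$p, unname(p_oracle), tolerance = 1e-9)
  expect_gt(ftab$odds_ratio, 1)

  expect_error(contingency_stats(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(contingency_stats(matrix(1:6, 2), "fisher2x2"), "2 x 2")
})

test_that("duplicate-column patients always cluster adjacently", {
  sim <- small_cohort()
  X <- em_values(sim$expr)
  tumor <- sim$annot[sim$annot$tissue == "tumor", ]
  # construct a cohort where one patient's two samples are exact duplicates
  ids <- tumor$sample_id[1:20]
  Xd <- X[, ids]
  Xd[, 2] <- Xd[, 1]
  annot <- cohort_annotation(data.frame(
    sample_id = ids,
    patient_id = c("DUP", "DUP", tumor$patient_id[3:20]),
    tissue = "tumor", stringsAsFactors = FALSE))
  db <- dendrogram_branch_analysis(expression_matrix(Xd), annot,
                                   n_branches = 4)
  cat_dup <- db$categories$category[db$categories$patient_id == "DUP"]
  expect_equal(cat_dup, "adjacent")
  expect_error(dendrogram_branch_analysis(expression_matrix(Xd), annot,
                                          n_branches = 100),
               "n_branches")
})

test_that("branch splitting increases with planted lesion switching", {
  frac <- vapply(c(0, 0.3, 0.6), function(hp) {
    cfg <- simulation_config(n_patients = 80, n_genes = 1000,
                             n_template_markers_per_subtype = 30,
                             mesenchymal_extra = 15, epithelial_shared = 15,
                             n_liver_genes = 50, heterogeneity_prob = hp,
                             contamination_alpha = c(1, 30),
                             lesions_per_patient = list(prob = 0.35, max = 4),
                             multiregion_frac = 0, seed = 42)
    sim <- generate_expression(cfg)
    contaminated <- apply_liver_contamination(sim$expr, sim$truth)
    db <- dendrogram_branch_analysis(contaminated, sim$annot)
    mean(db$categories$category == "split")
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], frac[1])
})

test_that("heterogeneity accounting follows the same-resection definition", {
  annot <- cohort_annotation(data.frame(
    sample_id = c("p1l1", "p1l2", "p2l1", "p2l2", "p3l1", "p3l1b", "p3l2",
                  "p4l1", "p4l2"),
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3", "P3", "P4", "P4"),
    lesion_id = c("P1_L1", "P1_L2", "P2_L1", "P2_L2", "P3_L1", "P3_L1",
                  "P3_L2", "P4_L1", "P4_L2"),
    region_id = c("R1", "R1", "R1", "R1", "R1", "R2", "R1", "R1", "R1"),
    resection_id = c("1", "1", "1", "1", "1", "1", "1", "1", "2"),
    tissue = "tumor", stringsAsFactors = FALSE))
  labels <- c(p1l1 = "LMS1", p1l2 = "LMS3",   # heterogeneous
              p2l1 = "LMS2", p2l2 = "LMS2",   # homogeneous
              p3l1 = "LMS4", p3l1b = "LMS5",  # intra-lesion heterogeneity
              p3l2 = "LMS4",
              p4l1 = "LMS1", p4l2 = "LMS2")   # lesions span two resections
  rep <- heterogeneity_report(labels, annot)
  pats <- rep$patients
  expect_true(pats$heterogeneous[pats$patient_id == "P1"])
  expect_false(pats$heterogeneous[pats$patient_id == "P2"])
  expect_equal(rep$excluded_patients, "P4")
  expect_equal(rep$n_eligible, 3)
  expect_equal(rep$fraction, 2 / 3)
  # P1 counts in both LMS1's and LMS3's per-subtype fractions
  expect_equal(unname(rep$per_subtype["LMS1"]), 1)
  expect_equal(unname(rep$per_subtype["LMS3"]), 1)
  expect_equal(unname(rep$per_subtype["LMS2"]), 0)
  # the multiregion lesion is flagged
  expect_true(rep$lesions$heterogeneous[rep$lesions$lesion_id == "P3_L1"])
  # all-same labels give fraction 0
  same <- setNames(rep_len("LMS2", length(labels)), names(labels))
  expect_equal(heterogeneity_report(same, annot)$fraction, 0)
})

test_that("the LMS1 survival association is robust to label switching", {
  sim <- small_cohort()
  annot <- sim$annot
  tumor <- annot[annot$tissue == "tumor", ]
  labels <- setNames(paste0("LMS", sim$truth$true_subtype),
                     names(sim$truth$true_subtype))
  pt <- tumor[!duplicated(tumor$patient_id), ]
  times <- setNames(pt$os_time_months, pt$patient_id)
  events <- setNames(pt$os_event, pt$patient_id)
  sw <- lms1_switch_sensitivity(labels, annot, times, events)
  expect_gt(sw$n_heterogeneous, 0)
  expect_true(all(sw$hr > 1))
  expect_equal(sw$hr_abs_difference, abs(sw$hr[1] - sw$hr[2]),
               ignore_attr = TRUE)
  # with no heterogeneous patients both fits coincide: give every sample its
  # patient's first-lesion label
  first_sub <- vapply(split(labels[tumor$sample_id], tumor$patient_id),
                      `[[`, character(1), 1)
  homo <- setNames(first_sub[tumor$patient_id], tumor$sample_id)
  sw2 <- lms1_switch_sensitivity(homo, annot, times, events)
  expect_equal(sw2$n_heterogeneous, 0)
  expect_match(sw2$note, "identical")
  expect_equal(sw2$hr[[1]], sw2$hr[[2]])
})
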