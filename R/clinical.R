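#' Dendrogram branch analysis of multi-sample patients
#'
#' Hierarchical clustering (Manhattan distance, Ward "D2" linkage) of the
#' tumor samples from patients with at least two samples, on the top-SD
#' genes. The tree is cut into `n_branches` main branches, and each patient is
#' categorized: `adjacent` when their samples form an exclusive clade (a
#' subtree containing no other patient's samples),
#' `same_branch_nonadjacent` when all samples share one main branch without an
#' exclusive clade, else `split`.
#'
#' @param expr log2 [expression_matrix()]
#' @param annot `CohortAnnotation`
#' @param n_branches number of main branches to cut (default 5)
#' @param n_top top-SD genes used for the distance (default 1000, clipped to
#'   the gene count)
#' @return list with `categories` (data.frame: patient, n_samples, category),
#'   `hclust`, `branches` (named branch index per sample)
#' @export
dendrogram_branch_analysis <- function(expr, annot, n_branches = 5L,
                                       n_top = 1000L) {
  stopifnot(is_expression_matrix(expr))
  tumor <- annot[annot$tissue == "tumor" &
                 annot$sample_id %in% colnames(expr), , drop = FALSE]
  multi <- names(which(table(tumor$patient_id) >= 2L))
  use <- tumor[tumor$patient_id %in% multi, , drop = FALSE]
  if (nrow(use) < 2L) stop("no patients with at least 2 samples")
  if (n_branches > nrow(use))
    stop("n_branches exceeds the number of samples")
  X <- em_values(expr)[, use$sample_id, drop = FALSE]
  sds <- apply(X, 1L, stats::sd)
  keep <- order(sds, decreasing = TRUE)[seq_len(min(n_top, nrow(X)))]
  d <- stats::dist(t(X[keep, , drop = FALSE]), method = "manhattan")
  hc <- stats::hclust(d, method = "ward.D2")
  branches <- stats::cutree(hc, k = n_branches)
  clades <- node_leaf_sets(hc)

  cats <- vapply(multi, function(p) {
    s <- use$sample_id[use$patient_id == p]
    exclusive <- any(vapply(clades, function(lv) setequal(lv, s), logical(1L)))
    if (exclusive) return("adjacent")
    if (length(unique(branches[s])) == 1L) return("same_branch_nonadjacent")
    "split"
  }, character(1L))
  list(categories = data.frame(patient_id = multi,
                               n_samples = as.integer(table(use$patient_id)[multi]),
                               category = cats, row.names = NULL,
                               stringsAsFactors = FALSE),
       hclust = hc, branches = branches)
}

# leaf label sets of every internal node of an hclust tree
node_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    sets[[i]] <- c(if (kids[1L] < 0) hc$labels[-kids[1L]] else sets[[kids[1L]]],
                   if (kids[2L] < 0) hc$labels[-kids[2L]] else sets[[kids[2L]]])
  }
  sets
}

#' Intra-patient subtype heterogeneity report
#'
#' A patient is inter-metastatically heterogeneous when distinct lesions from
#' one hepatic resection carry at least two distinct subtype calls; a lesion
#' is intra-tumor heterogeneous when its multiregion samples disagree. The
#' headline fraction is computed over patients with two or more distinct
#' lesions from the same resection; patients whose multiple lesions span only
#' different resections are excluded from it and reported separately.
#' Per-subtype fractions are computed patient-wise among patients with at
#' least one same-resection lesion/sample carrying that subtype.
#'
#' @param labels named subtype calls per sample
#' @param annot `CohortAnnotation` with lesion / region / resection keys
#' @return list of class `HeterogeneityReport`: `patients` (per-patient
#'   table), `lesions` (multiregion lesions), `per_subtype` (heterogeneity
#'   fraction per subtype), `fraction` (headline), `n_eligible`,
#'   `excluded_patients`
#' @export
heterogeneity_report <- function(labels, annot) {
  tumor <- annot[annot$tissue == "tumor", , drop = FALSE]
  missing_l <- setdiff(tumor$sample_id, names(labels))
  if (length(missing_l))
    stop("labels missing for sample(s): ",
         paste(utils::head(missing_l, 5L), collapse = ", "))
  tumor$call <- as.character(labels[tumor$sample_id])
  tumor$resection_id[is.na(tumor$resection_id)] <- "1"

  # multiregion lesions: distinct calls among regions
  lesion_tab <- do.call(rbind, lapply(split(tumor, tumor$lesion_id), function(g)
    data.frame(lesion_id = g$lesion_id[1L], patient_id = g$patient_id[1L],
               n_regions = nrow(g), n_calls = length(unique(g$call)),
               heterogeneous = length(unique(g$call)) > 1L,
               stringsAsFactors = FALSE)))
  rownames(lesion_tab) <- NULL
  multiregion <- lesion_tab[lesion_tab$n_regions >= 2L, , drop = FALSE]

  per_patient <- lapply(split(tumor, tumor$patient_id), function(g) {
    res_groups <- split(g, g$resection_id)
    eligible_groups <- Filter(function(rg) length(unique(rg$lesion_id)) >= 2L,
                              res_groups)
    n_lesions <- length(unique(g$lesion_id))
    if (!length(eligible_groups)) {
      return(data.frame(patient_id = g$patient_id[1L], n_lesions = n_lesions,
                        n_samples = nrow(g),
                        calls = paste(sort(unique(g$call)), collapse = ","),
                        eligible = FALSE, heterogeneous = NA,
                        cross_resection_only = n_lesions >= 2L,
                        stringsAsFactors = FALSE))
    }
    het <- any(vapply(eligible_groups, function(rg) {
      lesion_calls <- lapply(split(rg$call, rg$lesion_id), unique)
      length(unique(unlist(lesion_calls))) >= 2L
    }, logical(1L)))
    data.frame(patient_id = g$patient_id[1L], n_lesions = n_lesions,
               n_samples = nrow(g),
               calls = paste(sort(unique(g$call)), collapse = ","),
               eligible = TRUE, heterogeneous = het,
               cross_resection_only = FALSE, stringsAsFactors = FALSE)
  })
  patients <- do.call(rbind, per_patient)
  rownames(patients) <- NULL
  eligible <- patients[patients$eligible, , drop = FALSE]
  fraction <- if (nrow(eligible)) mean(eligible$heterogeneous) else NA_real_

  # calls present in each eligible patient's same-resection lesion groups
  eligible_calls <- lapply(eligible$patient_id, function(p) {
    g <- tumor[tumor$patient_id == p, , drop = FALSE]
    keep_res <- names(Filter(function(lids) length(unique(lids)) >= 2L,
                             split(g$lesion_id, g$resection_id)))
    unique(g$call[g$resection_id %in% keep_res])
  })
  subtypes <- sort(unique(tumor$call))
  per_subtype <- vapply(subtypes, function(st) {
    with_st <- vapply(eligible_calls, function(cl) st %in% cl, logical(1L))
    if (!any(with_st)) return(NA_real_)
    mean(eligible$heterogeneous[with_st])
  }, numeric(1L))

  structure(list(patients = patients, lesions = multiregion,
                 per_subtype = per_subtype, fraction = fraction,
                 n_eligible = nrow(eligible),
                 excluded_patients =
                   patients$patient_id[patients$cross_resection_only]),
            class = "HeterogeneityReport")
}

#' Kaplan-Meier curves with pairwise log-rank tests
#'
#' Events after the truncation horizon (default 60 months, the 5-year
#' endpoint) are censored at the horizon before any testing. Pairwise
#' log-rank chi-squared statistics over all group pairs are BH-adjusted.
#'
#' @param times survival times in months
#' @param events 0/1 event indicators
#' @param groups group labels per subject
#' @param truncate_months truncation horizon (default 60; `Inf` disables)
#' @return list of class `SurvivalFit`: `km` (survfit object), `overall`
#'   (chisq, df, p), `pairwise` (data.frame with BH-adjusted p)
#' @export
km_logrank <- function(times, events, groups, truncate_months = 60) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  if (any(times < 0, na.rm = TRUE)) stop("negative survival times")
  tr <- truncate_survival(times, events, truncate_months)
  groups <- as.factor(groups)
  if (any(table(groups) == 0L)) stop("empty survival group")
  dat <- data.frame(time = tr$time, event = tr$event, group = groups)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  overall <- NULL
  pairwise <- NULL
  if (nlevels(groups) >= 2L) {
    sd_all <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
    overall <- c(chisq = unname(sd_all$chisq), df = nlevels(groups) - 1L,
                 p = stats::pchisq(sd_all$chisq, nlevels(groups) - 1L,
                                   lower.tail = FALSE))
    pairs <- utils::combn(levels(groups), 2L)
    pw <- apply(pairs, 2L, function(pr) {
      sub <- dat[dat$group %in% pr, , drop = FALSE]
      sub$group <- droplevels(sub$group)
      sdp <- survival::survdiff(survival::Surv(time, event) ~ group, data = sub)
      c(chisq = unname(sdp$chisq),
        p = stats::pchisq(sdp$chisq, 1L, lower.tail = FALSE))
    })
    pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                           chisq = pw["chisq", ], p = pw["p", ],
                           q = bh_adjust(pw["p", ]),
                           stringsAsFactors = FALSE)
  }
  structure(list(km = km, overall = overall, pairwise = pairwise,
                 truncate_months = truncate_months),
            class = "SurvivalFit")
}

truncate_survival <- function(times, events, horizon) {
  if (is.finite(horizon)) {
    events <- ifelse(times > horizon, 0, events)
    times <- pmin(times, horizon)
  }
  list(time = times, event = events)
}

#' Cox proportional hazards fit with diagnostics
#'
#' Partial-likelihood fit with the Efron tie approximation; Wald confidence
#' intervals and p-values per covariate, and a proportional-hazards check via
#' the scaled Schoenfeld residual trend test. Times are truncated at the
#' 5-year horizon first.
#'
#' @param times survival times in months
#' @param events 0/1 event indicators
#' @param covariates data.frame of covariates (no constants)
#' @param check_ph run the Schoenfeld-residual PH test (default TRUE)
#' @param truncate_months truncation horizon (default 60; `Inf` disables)
#' @return list of class `CoxFit`: `model`, `coefficients` (beta, HR, CI,
#'   Wald p per covariate), `ph` (per-covariate PH test, or NULL),
#'   `separation_flagged`
#' @export
cox_fit <- function(times, events, covariates, check_ph = TRUE,
                    truncate_months = 60) {
  covariates <- as.data.frame(covariates)
  n_unique <- vapply(covariates, function(v) length(unique(v)), integer(1L))
  if (any(n_unique < 2L))
    stop("constant covariate(s): ",
         paste(colnames(covariates)[n_unique < 2L], collapse = ", "))
  tr <- truncate_survival(times, events, truncate_months)
  if (sum(tr$event) < ncol(covariates))
    stop("fewer events than covariates")
  dat <- cbind(data.frame(.time = tr$time, .event = tr$event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(colnames(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (!is.null(fit$info) && isTRUE(grepl("did not converge", fit$info)))
    stop("Cox model did not converge")
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      beta = sm$coefficients[, "coef"],
                      hr = sm$coefficients[, "exp(coef)"],
                      ci_lower = sm$conf.int[, "lower .95"],
                      ci_upper = sm$conf.int[, "upper .95"],
                      p = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  separation <- any(abs(coefs$beta) > 15)
  if (separation) warning("possible complete separation: extreme coefficient")
  ph <- NULL
  if (check_ph) {
    zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
    if (!is.null(zph)) {
      ph <- data.frame(term = rownames(zph$table),
                       chisq = zph$table[, "chisq"], p = zph$table[, "p"],
                       row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  structure(list(model = fit, coefficients = coefs, ph = ph,
                 separation_flagged = separation),
            class = "CoxFit")
}

#' Contingency-table statistics
#'
#' Pearson chi-squared without continuity correction (df = (r-1)(c-1)), or
#' Fisher's exact test with the conditional-MLE odds ratio (2 x 2 tables
#' only).
#'
#' @param counts non-negative integer matrix (or `table`)
#' @param test `"chi2"` or `"fisher2x2"`
#' @return list with `statistic` (chi2 only), `df`, `p`, `odds_ratio`
#'   (fisher only), `method`
#' @export
contingency_stats <- function(counts, test = c("chi2", "fisher2x2")) {
  test <- match.arg(test)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in contingency table")
  if (test == "chi2") {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value, odds_ratio = NULL, method = "Pearson chi-squared")
  } else {
    if (!all(dim(counts) == c(2L, 2L)))
      stop("Fisher's exact test supported for 2 x 2 tables only")
    ft <- stats::fisher.test(counts)
    list(statistic = NULL, df = NULL, p = ft$p.value,
         odds_ratio = unname(ft$estimate), method = "Fisher exact")
  }
}

#' Sensitivity of the LMS1 survival association to label switching
#'
#' Patients with inter-metastatic LMS1 heterogeneity (at least one LMS1 and
#' one non-LMS1 sample) are alternately counted in the LMS1 group (fit "a")
#' and in the LMS2-5 group (fit "b"); both LMS1-versus-rest Cox fits and the
#' absolute hazard-ratio difference are returned.
#'
#' @param labels named subtype calls per sample
#' @param annot `CohortAnnotation`
#' @param times named patient-level survival times (months)
#' @param events named patient-level 0/1 event indicators
#' @param truncate_months truncation horizon (default 60)
#' @return list with `fit_lms1_inclusive`, `fit_lms1_strict`, `hr` (both),
#'   `hr_abs_difference`, `n_heterogeneous`, `note`
#' @export
lms1_switch_sensitivity <- function(labels, annot, times, events,
                                    truncate_months = 60) {
  tumor <- annot[annot$tissue == "tumor", , drop = FALSE]
  tumor <- tumor[tumor$sample_id %in% names(labels), , drop = FALSE]
  tumor$call <- as.character(labels[tumor$sample_id])
  patients <- intersect(names(times), unique(tumor$patient_id))
  if (!length(patients)) stop("no patients with both labels and survival")
  any_lms1 <- vapply(patients, function(p)
    any(tumor$call[tumor$patient_id == p] == "LMS1"), logical(1L))
  all_lms1 <- vapply(patients, function(p)
    all(tumor$call[tumor$patient_id == p] == "LMS1"), logical(1L))
  het <- any_lms1 & !all_lms1
  note <- if (!any(het)) "no LMS1-heterogeneous patients; fits identical"
          else NULL
  fit_a <- cox_fit(times[patients], events[patients],
                   data.frame(lms1 = as.numeric(any_lms1)),
                   truncate_months = truncate_months)
  fit_b <- cox_fit(times[patients], events[patients],
                   data.frame(lms1 = as.numeric(all_lms1)),
                   truncate_months = truncate_months)
  hr <- c(inclusive = fit_a$coefficients$hr[1L],
          strict = fit_b$coefficients$hr[1L])
  list(fit_lms1_inclusive = fit_a, fit_lms1_strict = fit_b, hr = hr,
       hr_abs_difference = abs(diff(hr)), n_heterogeneous = sum(het),
       note = note)
}
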