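#' Simulation configuration for synthetic CRLM cohorts
#'
#' Defines a cohort with planted subtype structure mirroring the structure the
#' subtyping pipeline assumes: several epithelial-like subtypes plus one
#' mesenchymal-like subtype carrying an extra stromal expression block, a
#' liver-contamination gradient per sample, multi-lesion patients with
#' controllable inter-metastatic subtype switching, subtype-enriched mutation
#' flags, and subtype-dependent survival.
#'
#' Defaults reflect a resected-CRLM cohort: 169 patients, subtype prevalences
#' 18/10/19/30/24 percent (normalized), a planted hazard ratio of 2.2 for
#' subtype 1, KRAS mutation odds ratio 3.9 in subtype 1, TP53 odds ratio 0.2
#' in the mesenchymal subtype, 157 liver-enriched genes, and a lesion-switch
#' probability tuned so about half of multi-lesion patients are heterogeneous.
#'
#' @param n_patients number of patients with tumor samples
#' @param n_normal number of non-malignant liver tissue samples
#' @param n_genes total genes in the simulated universe
#' @param n_template_markers_per_subtype marker genes elevated in each subtype
#' @param mesenchymal_extra size of the additional stromal block carried by
#'   the mesenchymal subtype (`K_true`)
#' @param epithelial_shared size of the shared epithelial block elevated in
#'   subtypes 1..K_true-1 and low in the mesenchymal subtype; together with
#'   the stromal block it plants the primary epithelial-mesenchymal axis
#' @param n_liver_genes size of the liver-enriched block (near-zero in tumor
#'   signal, high in the liver profile)
#' @param K_true planted number of subtypes
#' @param subtype_prevalences probabilities per subtype, summing to 1
#' @param marker_fold linear-scale fold elevation of a subtype's markers
#' @param noise_sd log2-scale Gaussian noise SD per sample
#' @param patient_effect_sd log2-scale SD of a per-gene patient random effect
#'   shared by all samples of a patient; makes a patient's lesions more
#'   similar to each other than to other patients of the same subtype, as
#'   observed in multi-lesion cohorts
#' @param contamination_alpha `c(shape1, shape2)` of the Beta distribution of
#'   the per-sample liver fraction alpha in \[0, 1\]
#' @param lesions_per_patient list with `prob` (geometric success probability;
#'   lesion count is `1 + Geom(prob)`) and `max` (truncation, default 8)
#' @param heterogeneity_prob probability that each lesion after the first
#'   switches subtype; scalar or per-subtype vector (indexed by the patient's
#'   first-lesion subtype)
#' @param multiregion_frac fraction of lesions sampled in 2-4 regions
#' @param re_resection_frac fraction of multi-lesion patients whose last
#'   lesion comes from a later hepatic re-resection
#' @param hr_lms1 planted hazard ratio for patients with any subtype-1 lesion
#' @param baseline_median_survival_months median survival of the reference group
#' @param censor_rate target marginal fraction of censored patients
#' @param mutation_model list with `base` (named baseline mutation
#'   probabilities) and `or` (K x mutation odds-ratio matrix)
#' @param neoadjuvant_base baseline probability of neoadjuvant exposure
#' @param neoadjuvant_or_mesenchymal odds multiplier for the mesenchymal subtype
#' @param msi_prob per-subtype probability of MSI-high status
#' @param seed integer seed; fixed seed implies full reproducibility
#' @return object of class `SimulationConfig`
#' @export
simulation_config <- function(n_patients = 169,
                              n_normal = 19,
                              n_genes = 5000,
                              n_template_markers_per_subtype = 100,
                              mesenchymal_extra = 60,
                              epithelial_shared = 60,
                              n_liver_genes = 157,
                              K_true = 5,
                              subtype_prevalences = c(18, 10, 19, 30, 24) / 101,
                              marker_fold = 8,
                              noise_sd = 0.3,
                              patient_effect_sd = 0.2,
                              contamination_alpha = c(1, 3),
                              lesions_per_patient = list(prob = 0.73, max = 8),
                              heterogeneity_prob = 0.5,
                              multiregion_frac = 0.10,
                              re_resection_frac = 0.04,
                              hr_lms1 = 2.2,
                              baseline_median_survival_months = 40,
                              censor_rate = 0.3,
                              mutation_model = NULL,
                              neoadjuvant_base = 0.70,
                              neoadjuvant_or_mesenchymal = 3,
                              msi_prob = NULL,
                              seed = 1L) {
  if (abs(sum(subtype_prevalences) - 1) > 1e-9)
    stop("subtype_prevalences must sum to 1")
  if (length(subtype_prevalences) != K_true)
    stop("subtype_prevalences must have length K_true")
  if (any(subtype_prevalences < 0)) stop("prevalences must be non-negative")
  if (n_patients < K_true)
    stop("n_patients must be at least K_true so every subtype can occur")
  counts <- c(n_patients = n_patients, n_genes = n_genes, K_true = K_true,
              n_template_markers_per_subtype = n_template_markers_per_subtype,
              n_liver_genes = n_liver_genes)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (length(contamination_alpha) != 2L || any(contamination_alpha <= 0))
    stop("contamination_alpha must be two positive Beta shape parameters")
  n_marker_total <- K_true * n_template_markers_per_subtype +
    mesenchymal_extra + epithelial_shared + n_liver_genes
  if (n_genes <= n_marker_total)
    stop("n_genes must exceed the marker + liver blocks")
  if (length(heterogeneity_prob) == 1L)
    heterogeneity_prob <- rep(heterogeneity_prob, K_true)
  if (any(heterogeneity_prob < 0 | heterogeneity_prob > 1))
    stop("heterogeneity_prob must lie in [0, 1]")
  if (is.null(mutation_model)) {
    or <- matrix(1, K_true, 4,
                 dimnames = list(NULL, c("kras", "nras", "braf_v600e", "tp53")))
    or[1L, "kras"] <- 3.9
    or[K_true, "tp53"] <- 0.2
    mutation_model <- list(
      base = c(kras = 0.35, nras = 0.05, braf_v600e = 0.03, tp53 = 0.70),
      or = or)
  }
  if (is.null(msi_prob)) {
    msi_prob <- rep(0, K_true)
    msi_prob[1L] <- 0.03
  }
  structure(list(
    n_patients = n_patients, n_normal = n_normal, n_genes = n_genes,
    n_template_markers_per_subtype = n_template_markers_per_subtype,
    mesenchymal_extra = mesenchymal_extra,
    epithelial_shared = epithelial_shared, n_liver_genes = n_liver_genes,
    K_true = K_true, subtype_prevalences = subtype_prevalences,
    marker_fold = marker_fold, noise_sd = noise_sd,
    patient_effect_sd = patient_effect_sd,
    contamination_alpha = contamination_alpha,
    lesions_per_patient = lesions_per_patient,
    heterogeneity_prob = heterogeneity_prob,
    multiregion_frac = multiregion_frac,
    re_resection_frac = re_resection_frac,
    hr_lms1 = hr_lms1,
    baseline_median_survival_months = baseline_median_survival_months,
    censor_rate = censor_rate, mutation_model = mutation_model,
    neoadjuvant_base = neoadjuvant_base,
    neoadjuvant_or_mesenchymal = neoadjuvant_or_mesenchymal,
    msi_prob = msi_prob, seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Generate a synthetic expression cohort with planted subtypes
#'
#' Builds a linear-scale signal `S = W_true %*% H_true` from hard subtype
#' memberships: each subtype elevates its marker block by `marker_fold`, the
#' mesenchymal subtype (`K_true`) additionally carries a stromal block, a
#' liver-enriched block is near-zero in tumor signal, and background genes are
#' shared with the liver profile. Expression is `log2(S + 1)` plus Gaussian
#' noise. Non-malignant liver samples are drawn from the liver profile. The
#' returned matrix is uncontaminated; apply
#' [apply_liver_contamination()] with `truth$true_alpha` to add the
#' hepatocyte-infiltration gradient.
#'
#' @param config [simulation_config()]
#' @return list with `expr` (log2 `ExpressionMatrix`, tumor + normal columns),
#'   `annot` (sample skeleton, see [generate_clinical()] for clinical fields),
#'   and `truth` (`SyntheticTruth`: per-lesion subtypes, per-sample alpha,
#'   `W_true`, `H_true`, liver profile, marker map)
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  K <- config$K_true
  samples <- draw_sample_table(config)
  tumor <- samples[samples$tissue == "tumor", , drop = FALSE]

  m <- config$n_template_markers_per_subtype
  marker_map <- lapply(seq_len(K), function(k) sprintf("MK%d_%03d", k, seq_len(m)))
  names(marker_map) <- paste0("SUBTYPE", seq_len(K))
  stroma <- sprintf("STR_%03d", seq_len(config$mesenchymal_extra))
  epi <- sprintf("EPI_%03d", seq_len(config$epithelial_shared))
  liver_genes <- sprintf("LIV_%03d", seq_len(config$n_liver_genes))
  n_bg <- config$n_genes - K * m - config$mesenchymal_extra -
    config$epithelial_shared - config$n_liver_genes
  bg <- sprintf("BG_%04d", seq_len(n_bg))
  genes <- c(unlist(marker_map, use.names = FALSE), stroma, epi,
             liver_genes, bg)

  # linear-scale archetypes (genes x K)
  marker_base <- 2^stats::rnorm(K * m, mean = 5, sd = 0.5)
  stroma_base <- 2^stats::rnorm(length(stroma), mean = 5, sd = 0.5)
  epi_base <- 2^stats::rnorm(length(epi), mean = 5, sd = 0.5)
  bg_base <- 2^stats::rnorm(n_bg, mean = 6, sd = 1)
  W <- matrix(0, length(genes), K, dimnames = list(genes, NULL))
  for (k in seq_len(K)) {
    W[unlist(marker_map, use.names = FALSE), k] <- marker_base
    W[marker_map[[k]], k] <- marker_base[(k - 1L) * m + seq_len(m)] * config$marker_fold
    W[stroma, k] <- stroma_base
    W[epi, k] <- if (k < K) epi_base * config$marker_fold else epi_base
    W[liver_genes, k] <- 1
    W[bg, k] <- bg_base
  }
  W[stroma, K] <- stroma_base * config$marker_fold

  liver_profile <- stats::setNames(numeric(length(genes)), genes)
  liver_profile[unlist(marker_map, use.names = FALSE)] <- 2
  liver_profile[stroma] <- 2
  liver_profile[epi] <- 2
  liver_profile[liver_genes] <- 2^stats::rnorm(length(liver_genes), mean = 9, sd = 0.7)
  liver_profile[bg] <- bg_base

  H <- matrix(0, K, nrow(tumor))
  H[cbind(tumor$true_subtype, seq_len(nrow(tumor)))] <- 1
  colnames(H) <- tumor$sample_id

  S <- W %*% H
  liver_log2 <- log2(liver_profile + 1)
  normal_ids <- samples$sample_id[samples$tissue == "normal_liver"]
  X <- log2(S + 1)
  if (length(normal_ids)) {
    X <- cbind(X, matrix(liver_log2, length(genes), length(normal_ids),
                         dimnames = list(genes, normal_ids)))
  }
  if (config$patient_effect_sd > 0) {
    pats <- unique(tumor$patient_id)
    pe <- matrix(stats::rnorm(length(genes) * length(pats), 0,
                              config$patient_effect_sd),
                 length(genes), length(pats), dimnames = list(genes, pats))
    X[, tumor$sample_id] <- X[, tumor$sample_id] +
      pe[, tumor$patient_id, drop = FALSE]
  }
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd),
                    nrow(X), ncol(X))
  expr <- expression_matrix(X, scale_flag = "log2")

  alpha <- stats::setNames(
    stats::rbeta(nrow(tumor), config$contamination_alpha[1L],
                 config$contamination_alpha[2L]),
    tumor$sample_id)

  truth <- structure(list(
    samples = samples,
    true_subtype = stats::setNames(tumor$true_subtype, tumor$sample_id),
    true_alpha = alpha,
    W_true = W, H_true = H,
    liver_profile = liver_profile, liver_log2 = liver_log2,
    marker_map = marker_map, stroma_genes = stroma,
    epithelial_genes = epi,
    liver_genes = liver_genes, background_genes = bg,
    config = config), class = "SyntheticTruth")
  list(expr = expr, annot = cohort_annotation(samples[, c("sample_id",
       "patient_id", "tissue", "lesion_id", "region_id", "resection_id")]),
       truth = truth)
}

# patient / lesion / region structure and true subtypes
draw_sample_table <- function(config) {
  K <- config$K_true
  lp <- config$lesions_per_patient
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", i)
    n_lesions <- min(1L + stats::rgeom(1L, lp$prob), lp$max)
    k0 <- sample.int(K, 1L, prob = config$subtype_prevalences)
    subtypes <- integer(n_lesions)
    subtypes[1L] <- k0
    if (n_lesions > 1L) {
      for (l in 2:n_lesions) {
        if (stats::runif(1L) < config$heterogeneity_prob[k0]) {
          subtypes[l] <- sample(setdiff(seq_len(K), k0), 1L)
        } else subtypes[l] <- k0
      }
    }
    re_resected <- n_lesions > 1L &&
      stats::runif(1L) < config$re_resection_frac
    for (l in seq_len(n_lesions)) {
      lid <- sprintf("%s_L%d", pid, l)
      n_regions <- if (stats::runif(1L) < config$multiregion_frac)
        sample(2:4, 1L) else 1L
      res_id <- if (re_resected && l == n_lesions) "2" else "1"
      for (r in seq_len(n_regions)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_R%d", lid, r), patient_id = pid,
          lesion_id = lid, region_id = sprintf("R%d", r),
          resection_id = res_id, tissue = "tumor",
          true_subtype = subtypes[l], stringsAsFactors = FALSE)
      }
    }
  }
  for (j in seq_len(config$n_normal)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("N%03d", j), patient_id = sprintf("NP%03d", j),
      lesion_id = NA_character_, region_id = NA_character_,
      resection_id = NA_character_, tissue = "normal_liver",
      true_subtype = NA_integer_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Mix tumor expression with the liver profile
#'
#' Models hepatocyte contamination as a two-component convex mixture on the
#' linear scale: per sample `x' = log2((1 - alpha) * 2^x + alpha * 2^liver)`.
#' `alpha = 0` is the identity; `alpha = 1` returns the liver profile.
#'
#' @param expr log2-scale [expression_matrix()]
#' @param truth `SyntheticTruth` carrying the liver profile
#' @param alphas named per-sample liver fractions in \[0, 1\]; only named
#'   samples are mixed (defaults to `truth$true_alpha`)
#' @return contaminated log2 `ExpressionMatrix`
#' @export
apply_liver_contamination <- function(expr, truth, alphas = truth$true_alpha) {
  stopifnot(is_expression_matrix(expr), em_scale(expr) == "log2")
  if (any(alphas < 0 | alphas > 1)) stop("alpha must lie in [0, 1]")
  missing_s <- setdiff(names(alphas), colnames(expr))
  if (length(missing_s))
    stop("samples not in matrix: ", paste(missing_s, collapse = ", "))
  liver <- truth$liver_log2[rownames(expr)]
  if (anyNA(liver)) stop("liver profile does not cover all matrix genes")
  X <- em_values(expr)
  idx <- match(names(alphas), colnames(X))
  X[, idx] <- log2(sweep(2^X[, idx, drop = FALSE], 2, 1 - alphas, `*`) +
                   outer(2^liver, alphas))
  expression_matrix(X, scale_flag = "log2")
}

#' Generate clinical and survival annotation for a synthetic cohort
#'
#' Patient-level survival follows an exponential hazard multiplied by
#' `hr_lms1` when any lesion carries subtype 1, with independent exponential
#' censoring calibrated so the marginal censored fraction matches
#' `censor_rate`; proportional hazards therefore hold by construction.
#' Mutation flags are drawn with subtype-specific odds multipliers, MSI status
#' with per-subtype probabilities, and neoadjuvant exposure with elevated odds
#' for the mesenchymal subtype.
#'
#' @param truth `SyntheticTruth` from [generate_expression()]
#' @param config the same [simulation_config()]
#' @return `CohortAnnotation` with clinical, mutation and survival fields
#' @export
generate_clinical <- function(truth, config) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(config$seed + 1L)
  samples <- truth$samples
  tumor <- samples[samples$tissue == "tumor", , drop = FALSE]
  patients <- unique(tumor$patient_id)
  first_subtype <- vapply(patients, function(p)
    tumor$true_subtype[tumor$patient_id == p][1L], integer(1L))
  any_lms1 <- vapply(patients, function(p)
    any(tumor$true_subtype[tumor$patient_id == p] == 1L), logical(1L))

  lambda0 <- log(2) / config$baseline_median_survival_months
  rate <- lambda0 * ifelse(any_lms1, config$hr_lms1, 1)
  event_t <- stats::rexp(length(patients), rate)
  if (config$censor_rate >= 1) {
    cens_t <- stats::rexp(length(patients), lambda0 * 1e6) # censor ~immediately
    os_time <- cens_t; os_event <- rep(0, length(patients))
  } else if (config$censor_rate <= 0) {
    os_time <- event_t; os_event <- rep(1, length(patients))
  } else {
    lambda_c <- config$censor_rate / (1 - config$censor_rate) * lambda0
    cens_t <- stats::rexp(length(patients), lambda_c)
    os_time <- pmin(event_t, cens_t)
    os_event <- as.numeric(event_t <= cens_t)
  }
  cancer_death <- stats::runif(length(patients)) < 0.85
  css_event <- as.numeric(os_event == 1 & cancer_death)

  mm <- config$mutation_model
  draw_mut <- function(gene) {
    orv <- mm$or[first_subtype, gene]
    p <- stats::plogis(stats::qlogis(mm$base[[gene]]) + log(orv))
    stats::runif(length(patients)) < p
  }
  mut <- lapply(c("kras", "nras", "braf_v600e", "tp53"), draw_mut)
  names(mut) <- c("kras", "nras", "braf_v600e", "tp53")
  msi <- ifelse(stats::runif(length(patients)) < config$msi_prob[first_subtype],
                "MSI", "MSS")
  neo <- stats::runif(length(patients)) <
    stats::plogis(stats::qlogis(config$neoadjuvant_base) +
                  log(config$neoadjuvant_or_mesenchymal) *
                    (first_subtype == config$K_true))
  resec <- sample(c("R0", "R1", "R2"), length(patients), replace = TRUE,
                  prob = c(0.42, 0.53, 0.05))
  extra_hep <- stats::runif(length(patients)) < 0.23

  pt <- data.frame(patient_id = patients, neoadjuvant = neo,
                   resection = resec, extra_hepatic = extra_hep, msi = msi,
                   mut_kras = mut$kras, mut_nras = mut$nras,
                   mut_braf_v600e = mut$braf_v600e, mut_tp53 = mut$tp53,
                   os_time_months = os_time, os_event = os_event,
                   css_time_months = os_time, css_event = css_event,
                   stringsAsFactors = FALSE)
  annot <- merge(samples[, c("sample_id", "patient_id", "lesion_id",
                             "region_id", "resection_id", "tissue")],
                 pt, by = "patient_id", all.x = TRUE, sort = FALSE)
  annot <- annot[match(samples$sample_id, annot$sample_id), ]
  rownames(annot) <- NULL
  cohort_annotation(annot)
}

#' Generate gene-set stand-ins for a synthetic cohort
#'
#' Emits the liver-enriched set (size `n_liver_genes`, default 157), one
#' marker set per subtype, named signature aliases used for subtype naming
#' (mesenchymal, secretory/MSI-like, stem, enterocyte, epithelial), smaller
#' MSI-like and KRAS-addiction subsets of the subtype-1 markers, and random
#' decoy sets drawn from the background genes.
#'
#' @param truth `SyntheticTruth`
#' @param n_decoys number of decoy sets (default 20)
#' @param decoy_size genes per decoy set (default 25)
#' @return `GeneSetCollection`
#' @export
generate_genesets <- function(truth, n_decoys = 20, decoy_size = 25) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(truth$config$seed + 2L)
  K <- truth$config$K_true
  mm <- truth$marker_map
  sets <- stats::setNames(mm, paste0(names(mm), "_MARKERS"))
  sets$LIVER_ENRICHED <- truth$liver_genes
  sets$MESENCHYMAL <- c(truth$stroma_genes, mm[[K]])
  sets$EPITHELIAL <- truth$epithelial_genes
  sets$SECRETORY_MSI_LIKE <- mm[[1L]]
  if (K >= 2L) sets$STEM <- mm[[2L]]
  if (K >= 4L) sets$ENTEROCYTE <- mm[[4L]]
  sets$MSI_LIKE <- mm[[1L]][seq_len(min(30L, length(mm[[1L]])))]
  sets$KRAS_ADDICTION <- mm[[1L]][rev(seq_along(mm[[1L]]))][seq_len(min(30L, length(mm[[1L]])))]
  for (d in seq_len(n_decoys)) {
    sets[[sprintf("DECOY_%02d", d)]] <-
      sample(truth$background_genes, decoy_size)
  }
  gene_set_collection(sets)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_expression()],
#' [apply_liver_contamination()], [generate_clinical()] and
#' [generate_genesets()].
#'
#' @param config [simulation_config()]
#' @param contaminate apply the liver-contamination mixture (default TRUE)
#' @return list with `expr` (contaminated), `expr_clean`, `annot`, `truth`,
#'   `sets`
#' @export
simulate_cohort <- function(config = simulation_config(), contaminate = TRUE) {
  gen <- generate_expression(config)
  expr <- gen$expr
  if (contaminate)
    expr <- apply_liver_contamination(gen$expr, gen$truth)
  annot <- generate_clinical(gen$truth, config)
  sets <- generate_genesets(gen$truth)
  list(expr = expr, expr_clean = gen$expr, annot = annot,
       truth = gen$truth, sets = sets)
}
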