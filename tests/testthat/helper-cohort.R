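# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# compact 5-subtype cohort for unit tests
small_cohort <- function() {
  memo("small", function() {
    cfg <- simulation_config(n_patients = 60, n_genes = 1200,
                             n_template_markers_per_subtype = 30,
                             mesenchymal_extra = 15, epithelial_shared = 15,
                             n_liver_genes = 50, seed = 7)
    simulate_cohort(cfg)
  })
}

# full-size cohort at the discovery scale, with the complete discovery chain
# (one sample per patient, template selection, consensus at K = 4..6)
discovery_cohort <- function() {
  memo("discovery", function() {
    cfg <- simulation_config(seed = 101)
    sim <- simulate_cohort(cfg)
    picks <- select_one_sample_per_patient(sim$annot, seed = 202)
    X <- em_values(sim$expr)
    tum <- expression_matrix(X[, picks, drop = FALSE])
    nor <- expression_matrix(
      X[, sim$annot$sample_id[sim$annot$tissue == "normal_liver"],
        drop = FALSE])
    sel <- select_template_genes(tum, nor)
    V <- as_linear(expression_matrix(
      em_values(tum)[sel$template_genes, , drop = FALSE]))
    res <- lapply(4:6, function(K)
      consensus_cluster(V, K, n_runs = 30, seed = 303))
    names(res) <- as.character(4:6)
    list(sim = sim, picks = picks, tum = tum, nor = nor, sel = sel, V = V,
         consensus = res)
  })
}

# random labeled expression matrix
rand_expr <- function(G, n, seed = 1, mean = 5, sd = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(G * n, mean, sd), G, n,
              dimnames = list(sprintf("G%04d", seq_len(G)),
                              sprintf("S%03d", seq_len(n))))
  expression_matrix(X)
}

# Hubert-Arabie adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maximum <- (si + sj) / 2
  (sij - expected) / (maximum - expected)
}

# brute-force BH step-up straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(m * sort(p)[r[i]:m] / (r[i]:m)))
  }, numeric(1L))
}
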