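# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# small multi-batch cohort reused across module tests
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(sim_config(
      n_genes = 100, n_pathways = 10, pathway_size_range = c(8, 12),
      n_cell_samples = 120, n_tumor_samples = 50, n_batches = 2,
      n_drugs = 3, effect_size = 1.5, noise_sd = 0.4, seed = 42))
  }
  .fixture_env$cohort
}

# tiny expression matrix with explicit values
toy_expr <- function(values, batch = "b1", cancer = "BRCA") {
  expression_matrix(values, batch = batch, cancer_type = cancer)
}

# naive step-by-step running-sum ssGSEA oracle (independent of the package
# implementation: explicit loop over ranked genes)
oracle_ssgsea <- function(expr, set, alpha = 0, tie_seed = 1) {
  genes <- names(expr)
  N <- length(genes)
  tb <- withr::with_seed(tie_seed, sample(N))
  ord <- order(-expr, tb)
  ranked <- genes[ord]
  inset <- ranked %in% set
  m <- sum(inset)
  w <- ((N:1) / N)^alpha
  rs <- 0; total <- 0
  for (i in seq_len(N)) {
    if (inset[i]) rs <- rs + w[i] / sum(w[inset])
    else rs <- rs - 1 / (N - m)
    total <- total + rs
  }
  total
}

# brute-force pairwise-concordance AUROC oracle
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

expect_no_dup_rows <- function(tab) {
  expect_equal(anyDuplicated(tab[c("sample_id", "drug_id")]), 0L)
}
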