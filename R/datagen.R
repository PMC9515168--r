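# Synthetic multi-batch cohort generator with planted pathway-level
# drug-response signal. Every downstream stage (harmonization, ssGSEA, drug
# features, pre-training, transfer, explanation) is testable against the
# returned ground truth without any external download.

#' Simulation configuration
#'
#' Defaults describe a small but realistic two-domain study: a few hundred
#' cell-line samples across multiple batches, a small tumor cohort sharing
#' the same generative law, overlapping pathways over a modest gene universe,
#' and drugs whose response is driven by a handful of signal pathways.
#'
#' @param n_genes gene universe size.
#' @param n_pathways number of pathways.
#' @param pathway_size_range min/max pathway size (genes).
#' @param n_cell_samples cell-line sample count.
#' @param n_tumor_samples tumor sample count (small by design).
#' @param n_batches number of cell-line batches (tumors form one extra batch).
#' @param batch_shift_sd SD of per-batch-per-gene additive shifts.
#' @param batch_scale_range range of per-batch-per-gene multiplicative scales.
#' @param n_drugs number of drugs.
#' @param n_signal_pathways_per_drug signal pathways per drug.
#' @param effect_size magnitude of each signal pathway's weight on response.
#' @param noise_sd SD of gene-level expression noise and of response noise.
#' @param seed integer; fixes the full cohort bit-for-bit.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, n_pathways = 20,
                       pathway_size_range = c(8, 15),
                       n_cell_samples = 300, n_tumor_samples = 80,
                       n_batches = 2, batch_shift_sd = 1.0,
                       batch_scale_range = c(0.7, 1.4),
                       n_drugs = 5, n_signal_pathways_per_drug = 2,
                       effect_size = 1.5, noise_sd = 0.5, seed = 1) {
  cfg <- list(n_genes = n_genes, n_pathways = n_pathways,
              pathway_size_range = pathway_size_range,
              n_cell_samples = n_cell_samples, n_tumor_samples = n_tumor_samples,
              n_batches = n_batches, batch_shift_sd = batch_shift_sd,
              batch_scale_range = batch_scale_range, n_drugs = n_drugs,
              n_signal_pathways_per_drug = n_signal_pathways_per_drug,
              effect_size = effect_size, noise_sd = noise_sd, seed = seed)
  counts <- c(cfg$n_genes, cfg$n_pathways, cfg$n_cell_samples,
              cfg$n_tumor_samples, cfg$n_batches, cfg$n_drugs,
              cfg$n_signal_pathways_per_drug)
  if (any(counts <= 0)) stop2("all counts must be positive")
  if (cfg$noise_sd < 0) stop2("noise_sd must be >= 0")
  if (max(pathway_size_range) > n_genes)
    stop2("pathway_size_range exceeds n_genes")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic, chemically valid SMILES for synthetic drug i
synthetic_smiles <- function(i) {
  suffix <- c("O", "N", "C(=O)O")[((i - 1) %% 3) + 1]
  chain <- strrep("C", 1 + ((i - 1) %/% 3))
  paste0(chain, suffix)
}

#' Generate a synthetic two-domain cohort
#'
#' Latent per-sample pathway activities drive both member-gene expression and
#' drug response; batch effects are planted as gene-wise location/scale
#' distortions (the model empirical-Bayes batch adjustment assumes); drug
#' targets are drawn from each drug's signal pathways so that
#' network-propagated target features are informative. Cell and tumor samples
#' share the same generative law, which is what makes layer transfer from the
#' large cell cohort to the small tumor cohort beneficial.
#'
#' @param config a [sim_config()].
#' @return list with elements `cells`, `tumors` (expr_matrix), `gene_sets`,
#'   `drugs` (drug table), `ppi` (igraph), `resp_cells_cont`,
#'   `resp_tumors_dich`, `resp_tumors_cont` (response tables) and `truth`
#'   (per-drug signal pathways/weights and latent activities).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))

  # pathways: contiguous blocks covering the universe, plus random extras so
  # neighbouring pathways overlap
  block <- ceiling(cfg$n_genes / cfg$n_pathways)
  sets <- list()
  for (p in seq_len(cfg$n_pathways)) {
    size <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]), 1)
    start <- ((p - 1) * block) %% cfg$n_genes
    core <- genes[(start + seq_len(min(size, cfg$n_genes)) - 1) %% cfg$n_genes + 1]
    extra <- sample(genes, max(0, size - length(core) + 2))
    sets[[sprintf("PW%02d", p)]] <- unique(c(core, extra))
  }
  collection <- gene_sets(sets, provenance = "SYNTH")

  # gene -> pathway membership
  membership <- matrix(FALSE, cfg$n_genes, cfg$n_pathways,
                       dimnames = list(genes, names(sets)))
  for (p in names(sets)) membership[sets[[p]], p] <- TRUE

  n_all <- cfg$n_cell_samples + cfg$n_tumor_samples
  sample_ids <- c(sprintf("CL%04d", seq_len(cfg$n_cell_samples)),
                  sprintf("TU%04d", seq_len(cfg$n_tumor_samples)))
  is_cell <- c(rep(TRUE, cfg$n_cell_samples), rep(FALSE, cfg$n_tumor_samples))
  batch <- c(sprintf("cellbatch%d", ((seq_len(cfg$n_cell_samples) - 1) %% cfg$n_batches) + 1),
             rep("tumor", cfg$n_tumor_samples))
  cancer <- sample(c("BRCA", "LUAD", "COAD", "SKCM"), n_all, replace = TRUE)

  # latent pathway activities (samples x pathways)
  activity <- matrix(stats::rnorm(n_all * cfg$n_pathways), n_all, cfg$n_pathways,
                     dimnames = list(sample_ids, names(sets)))

  # expression = baseline + sum of member-pathway activities + noise,
  # then gene-wise batch location/scale distortion on the varying part
  baseline <- stats::rnorm(cfg$n_genes, mean = 7, sd = 1)
  signal <- (membership * 1) %*% t(activity)                 # genes x samples
  noise <- matrix(stats::rnorm(cfg$n_genes * n_all, sd = cfg$noise_sd),
                  cfg$n_genes, n_all)
  varying <- signal + noise
  batches <- unique(batch)
  shift <- matrix(stats::rnorm(cfg$n_genes * length(batches),
                               sd = cfg$batch_shift_sd),
                  cfg$n_genes, length(batches), dimnames = list(genes, batches))
  scale_ <- matrix(stats::runif(cfg$n_genes * length(batches),
                                cfg$batch_scale_range[1], cfg$batch_scale_range[2]),
                   cfg$n_genes, length(batches), dimnames = list(genes, batches))
  values <- matrix(0, cfg$n_genes, n_all, dimnames = list(genes, sample_ids))
  for (b in batches) {
    j <- batch == b
    values[, j] <- baseline + shift[, b] + scale_[, b] * varying[, j]
  }

  cells <- expression_matrix(values[, is_cell, drop = FALSE],
                             batch = batch[is_cell], cancer_type = cancer[is_cell])
  tumors <- expression_matrix(values[, !is_cell, drop = FALSE],
                              batch = batch[!is_cell], cancer_type = cancer[!is_cell])

  # PPI: dense within pathways, sparse across, weak ring for connectivity
  edges <- list(); k <- 0
  for (p in names(sets)) {
    mem <- sets[[p]]
    if (length(mem) < 2) next
    pairs <- utils::combn(mem, 2)
    pick <- stats::runif(ncol(pairs)) < 0.3
    if (any(pick)) { k <- k + 1; edges[[k]] <- cbind(t(pairs[, pick, drop = FALSE]),
                                                     stats::runif(sum(pick), 0.5, 1)) }
  }
  n_cross <- cfg$n_genes  # sparse background
  a <- sample(genes, n_cross, replace = TRUE)
  b2 <- sample(genes, n_cross, replace = TRUE)
  ok <- a != b2
  k <- k + 1
  edges[[k]] <- cbind(a[ok], b2[ok], stats::runif(sum(ok), 0.1, 0.4))
  k <- k + 1
  edges[[k]] <- cbind(genes, genes[c(2:cfg$n_genes, 1)],
                      rep(0.1, cfg$n_genes))
  edf <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edf[, 1], to = edf[, 2], weight = as.numeric(edf[, 3]),
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = genes)
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))

  # drugs: signal pathways, signed weights, targets from signal pathways
  drug_ids <- sprintf("d%02d", seq_len(cfg$n_drugs))
  truth_drugs <- list()
  targets <- vector("list", cfg$n_drugs)
  for (i in seq_len(cfg$n_drugs)) {
    sig <- sample(names(sets), cfg$n_signal_pathways_per_drug)
    w <- cfg$effect_size * sample(c(-1, 1), length(sig), replace = TRUE)
    names(w) <- sig
    truth_drugs[[drug_ids[i]]] <- list(pathways = sig, weights = w)
    pool <- unique(unlist(sets[sig]))
    targets[[i]] <- sample(pool, min(3, length(pool)))
  }
  drugs <- data.frame(drug_id = drug_ids,
                      smiles = vapply(seq_len(cfg$n_drugs), synthetic_smiles, character(1)),
                      stringsAsFactors = FALSE)
  drugs$targets <- targets

  # responses: logistic link over the weighted signal-pathway activities
  intercept <- stats::rnorm(cfg$n_drugs, 0, 1)
  make_cont <- function(ids) {
    out <- list()
    for (i in seq_len(cfg$n_drugs)) {
      w <- truth_drugs[[drug_ids[i]]]$weights
      lin <- activity[ids, names(w), drop = FALSE] %*% w + intercept[i]
      cont <- stats::plogis(lin) + stats::rnorm(length(ids), sd = cfg$noise_sd)
      out[[i]] <- data.frame(sample_id = ids, drug_id = drug_ids[i],
                             response = pmin(pmax(as.numeric(cont), 0), 1),
                             lin = as.numeric(lin), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  cc <- make_cont(sample_ids[is_cell])
  tc <- make_cont(sample_ids[!is_cell])

  resp_cells_cont <- response_table(cc$sample_id, cc$drug_id, cc$response,
                                    kind = "continuous")
  # alternative potency-style target for model selection experiments
  resp_cells_cont$neg_log10_ic50 <- cc$lin / log(10)

  resp_tumors_cont <- response_table(tc$sample_id, tc$drug_id, tc$response,
                                     kind = "continuous")
  med <- stats::ave(tc$response, tc$drug_id, FUN = stats::median)
  resp_tumors_dich <- response_table(tc$sample_id, tc$drug_id,
                                     as.numeric(tc$response > med),
                                     kind = "dichotomous")

  list(cells = cells, tumors = tumors, gene_sets = collection, drugs = drugs,
       ppi = g, resp_cells_cont = resp_cells_cont,
       resp_tumors_dich = resp_tumors_dich, resp_tumors_cont = resp_tumors_cont,
       truth = list(drugs = truth_drugs,
                    activity = activity,
                    batch_shift = shift, batch_scale = scale_),
       config = cfg)
}

#' Downsample responders to emulate a heavily imbalanced screen
#'
#' @param table dichotomous `response_table`.
#' @param responder_fraction target responders as a fraction of each drug's
#'   rows, in (0, 1].
#' @param seed RNG seed.
#' @return imbalanced `response_table`.
#' @export
make_imbalanced <- function(table, responder_fraction, seed = 1) {
  if (attr(table, "kind") != "dichotomous") stop2("need a dichotomous table")
  if (responder_fraction <= 0 || responder_fraction > 1)
    stop2("responder_fraction must be in (0, 1]")
  with_seed(seed, {
    keep <- logical(nrow(table))
    for (d in unique(table$drug_id)) {
      rows <- which(table$drug_id == d)
      resp <- rows[table$response[rows] == 1]
      n_keep <- min(length(resp), round(responder_fraction * length(rows)))
      keep[setdiff(rows, resp)] <- TRUE
      if (n_keep > 0) keep[sample(resp, n_keep)] <- TRUE
    }
    out <- table[keep, , drop = FALSE]
    attr(out, "kind") <- "dichotomous"
    class(out) <- class(table)
    rownames(out) <- NULL
    out
  })
}

#' Write all cohort artifacts to a directory
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$cells, file.path(dir, "cells.tsv"))
  write_expression(cohort$tumors, file.path(dir, "tumors.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "pathways.gmt"))
  write_drug_table(cohort$drugs, file.path(dir, "drugs.tsv"))
  write_edge_list(cohort$ppi, file.path(dir, "ppi.tsv"))
  write_response(cohort$resp_cells_cont, file.path(dir, "response_cells_cont.tsv"))
  write_response(cohort$resp_tumors_dich, file.path(dir, "response_tumors_dich.tsv"))
  write_response(cohort$resp_tumors_cont, file.path(dir, "response_tumors_cont.tsv"))
  truth <- cohort$truth
  truth$activity <- NULL  # large; regenerate from the seed instead
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
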