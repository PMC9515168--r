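# End-to-end orchestration on a synthetic cohort: simulate -> harmonize ->
# pathway features -> drug features -> pretrain -> transferred and
# non-transferred fine-tuning arms -> repeated CV comparison -> Shapley
# explanation. One run directory per invocation; a JSON report and a
# JSON-lines parameter log make every run auditable and reproducible.

#' Pipeline configuration
#'
#' Nested parameter blocks for every stage. All randomness derives from the
#' single `seed`.
#'
#' @param seed global seed.
#' @param sim a [sim_config()].
#' @param ssgsea list: weight_exponent, normalize, min_overlap, n_perm
#'   (0 = skip permutation p-values).
#' @param drug list: radius, n_bits, restart_prob, n_perm, null.
#' @param pretrain list: widths, max_epochs, batch_size, learning_rate.
#' @param transfer list: n_transfer_layers, retrain_transferred,
#'   new_hidden_layers, max_epochs, batch_size, learning_rate, dropout.
#' @param evaluate list: k, repeats, min_group_n.
#' @param explain list: n_perm, n_baseline, top_k, threshold.
#' @param arms list: transfer, baseline (logical toggles).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            sim = sim_config(seed = seed),
                            ssgsea = list(), drug = list(), pretrain = list(),
                            transfer = list(), evaluate = list(),
                            explain = list(), arms = list()) {
  merge_block <- function(defaults, user) utils::modifyList(defaults, user)
  cfg <- list(
    seed = seed, sim = sim,
    ssgsea = merge_block(list(weight_exponent = 0.25, normalize = FALSE,
                              min_overlap = 5, n_perm = 0), ssgsea),
    drug = merge_block(list(radius = 2, n_bits = 256, restart_prob = 0.5,
                            n_perm = 50, null = "uniform"), drug),
    pretrain = merge_block(list(widths = c(64, 32, 16, 8), max_epochs = 100,
                                batch_size = 128, learning_rate = 1e-3), pretrain),
    transfer = merge_block(list(n_transfer_layers = NULL,
                                retrain_transferred = TRUE,
                                new_hidden_layers = integer(0),
                                max_epochs = 100, batch_size = 32,
                                learning_rate = 4e-4, dropout = 0.1), transfer),
    evaluate = merge_block(list(k = 5, repeats = 5, min_group_n = 5), evaluate),
    explain = merge_block(list(n_perm = 4, n_baseline = 30, top_k = 10,
                               threshold = 0.5), explain),
    arms = merge_block(list(transfer = TRUE, baseline = TRUE), arms))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; missing keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1
  sim_args <- y$sim %||% list()
  sim_args$seed <- sim_args$seed %||% seed
  pipeline_config(seed = seed, sim = do.call(sim_config, sim_args),
                  ssgsea = y$ssgsea %||% list(), drug = y$drug %||% list(),
                  pretrain = y$pretrain %||% list(),
                  transfer = y$transfer %||% list(),
                  evaluate = y$evaluate %||% list(),
                  explain = y$explain %||% list(), arms = y$arms %||% list())
}

log_stage <- function(log_path, stage, params) {
  rec <- list(stage = stage, params = params)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE, sep = "")
}

# mean absolute between-batch gene-mean difference (harmonization diagnostic)
batch_mean_gap <- function(matrix) {
  batches <- unique(matrix$batch)
  if (length(batches) < 2) return(0)
  means <- vapply(batches, function(b)
    rowMeans(matrix$values[, matrix$batch == b, drop = FALSE]),
    numeric(nrow(matrix$values)))
  mean(apply(means, 1, function(v) max(v) - min(v)))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage in order and writes all artifacts, a `report.json`
#' with both arms' fold scores and their Mann-Whitney comparison, and a
#' `log.jsonl` recording the parameters each stage actually used. Reruns
#' with the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; must not contain a previous
#'   report).
#' @return the report, invisibly; artifacts under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("pathdrp_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  seed <- config$seed
  log_stage(log_path, "simulate", unclass(config$sim))
  cohort <- stage("simulate", generate_cohort(config$sim))
  write_cohort(cohort, file.path(out_dir, "cohort"))

  log_stage(log_path, "harmonize", list(n_batches = length(unique(
    c(cohort$cells$batch, cohort$tumors$batch)))))
  harmonized <- stage("harmonize", harmonize_run(list(cohort$cells, cohort$tumors)))
  gap_post <- batch_mean_gap(harmonized)
  write_expression(harmonized, file.path(out_dir, "harmonized.tsv"))

  log_stage(log_path, "exp_features", config$ssgsea)
  scores <- stage("exp_features", {
    s <- ssgsea_matrix(harmonized, cohort$gene_sets,
                       weight_exponent = config$ssgsea$weight_exponent,
                       normalize = config$ssgsea$normalize,
                       min_overlap = config$ssgsea$min_overlap)
    if (config$ssgsea$n_perm > 0)
      s <- permutation_significance(harmonized, cohort$gene_sets,
                                    n_perm = config$ssgsea$n_perm,
                                    seed = child_seed(seed, "ssgsea"),
                                    weight_exponent = config$ssgsea$weight_exponent,
                                    normalize = config$ssgsea$normalize,
                                    min_overlap = config$ssgsea$min_overlap)
    s
  })
  utils::write.table(scores$scores, file.path(out_dir, "exp_features.tsv"),
                     sep = "\t", quote = FALSE)

  log_stage(log_path, "drug_features", config$drug)
  chem <- stage("drug_features", chem_matrix(cohort$drugs, config$drug$radius,
                                             config$drug$n_bits))
  dgnet <- stage("drug_features",
                 dgnet_matrix(cohort$ppi, cohort$drugs, cohort$gene_sets,
                              restart_prob = config$drug$restart_prob,
                              n_perm = config$drug$n_perm,
                              null = config$drug$null,
                              seed = child_seed(seed, "dgnet")))
  utils::write.table(chem, file.path(out_dir, "chem.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(dgnet, file.path(out_dir, "dgnet.tsv"), sep = "\t", quote = FALSE)

  cancer <- stats::setNames(c(cohort$cells$cancer_type, cohort$tumors$cancer_type),
                            c(colnames(cohort$cells$values), colnames(cohort$tumors$values)))
  feats_cells <- build_feature_table(scores, chem, dgnet, cohort$resp_cells_cont,
                                     cancer_type = cancer)
  feats_tumor <- build_feature_table(scores, chem, dgnet, cohort$resp_tumors_dich,
                                     cancer_type = cancer)

  log_stage(log_path, "pretrain", config$pretrain)
  pre_cfg <- train_config(loss = "rmse", max_epochs = config$pretrain$max_epochs,
                          batch_size = config$pretrain$batch_size,
                          learning_rate = config$pretrain$learning_rate,
                          seed = child_seed(seed, "pretrain"))
  pretrained <- stage("pretrain", pretrain(feats_cells, pre_cfg,
                                           widths = config$pretrain$widths))
  save_model(pretrained, file.path(out_dir, "pretrained.json"))
  pretrain_rmse <- utils::tail(pretrained$log$val_loss, 1)

  tcfg <- config$transfer
  n_tl <- tcfg$n_transfer_layers %||% length(config$pretrain$widths)
  mk_train <- function(s) train_config(loss = "bce", max_epochs = tcfg$max_epochs,
                                       batch_size = tcfg$batch_size,
                                       learning_rate = tcfg$learning_rate,
                                       dropout = tcfg$dropout,
                                       val_fraction = 0.2, seed = s)
  arms <- list()
  if (isTRUE(config$arms$transfer)) {
    log_stage(log_path, "transfer_arm", tcfg)
    arms$transfer <- function(tr) {
      cfg <- transfer_config(n_transfer_layers = n_tl,
                             retrain_transferred = tcfg$retrain_transferred,
                             new_hidden_layers = tcfg$new_hidden_layers,
                             head = "classification",
                             train = mk_train(child_seed(seed, "finetune")),
                             seed = child_seed(seed, "transfer"))
      fine_tune(transfer_build(pretrained, cfg), tr, cfg)
    }
  }
  if (isTRUE(config$arms$baseline)) {
    log_stage(log_path, "baseline_arm", list(widths = config$pretrain$widths))
    arms$baseline <- function(tr) {
      m <- build_network(ncol(tr$x), head = "classification",
                         widths = config$pretrain$widths,
                         dropout = tcfg$dropout,
                         seed = child_seed(seed, "scratch"))
      fine_tune(m, tr, mk_train(child_seed(seed, "scratch_fit")))
    }
  }
  if (length(arms) == 0) stop2("both arms disabled")

  log_stage(log_path, "evaluate", config$evaluate)
  cv <- lapply(arms, function(fit)
    stage("evaluate", repeated_cv(feats_tumor, fit, metric = "auroc",
                                  k = config$evaluate$k,
                                  repeats = config$evaluate$repeats,
                                  seed = child_seed(seed, "cv"))))
  report <- list(
    seed = seed,
    harmonization = list(batch_mean_gap_post = gap_post),
    pretrain = list(final_val_rmse = pretrain_rmse,
                    epochs = nrow(pretrained$log)),
    arms = lapply(cv, function(r) list(
      metric = r$metric, fold_scores = r$fold_scores, mean = r$mean,
      sd = r$sd, mean_sd = format_mean_sd(r))))
  if (length(cv) == 2)
    report$comparison <- list(
      mwu_p_two_sided = compare_models(cv$transfer$fold_scores,
                                       cv$baseline$fold_scores),
      mwu_p_transfer_greater = compare_models(cv$transfer$fold_scores,
                                              cv$baseline$fold_scores,
                                              alternative = "greater"))
  first_cv <- cv[[1]]
  membership <- stats::setNames(rep(TRUE, length(unique(feats_tumor$drug_id))),
                                unique(feats_tumor$drug_id))
  per_drug <- per_group_performance(first_cv$predictions, "drug_id", membership,
                                    min_group_n = config$evaluate$min_group_n)
  report$per_drug <- per_drug$table

  log_stage(log_path, "explain", config$explain)
  expl <- stage("explain", {
    arm_fit <- arms[[1]]
    final <- arm_fit(feats_tumor)
    probs <- predict(final, feats_tumor$x)
    nb <- min(config$explain$n_baseline, nrow(feats_tumor$x))
    base_rows <- with_seed(child_seed(seed, "baseline_rows"),
                           sample(nrow(feats_tumor$x), nb))
    att <- shapley_values(final, feats_tumor$x[seq_len(min(40, nrow(feats_tumor$x))), ,
                                               drop = FALSE],
                          feats_tumor$x[base_rows, , drop = FALSE],
                          n_perm = config$explain$n_perm,
                          seed = child_seed(seed, "shap"))
    top <- rank_importance(att, top_k = config$explain$top_k,
                           features = feats_tumor$blocks$EXP)
    # per-drug responder (TP) vs non-responder (TN) pathway comparison
    per_drug <- lapply(unique(feats_tumor$drug_id), function(d) {
      it <- feats_tumor$drug_id == d
      cats <- suppressWarnings(categorize_predictions(
        feats_tumor$y[it], probs[it], threshold = config$explain$threshold,
        ids = feats_tumor$sample_id[it]))
      cmp <- if (length(cats$tp) >= 3 && length(cats$tn) >= 3)
        compare_groups(scores, cats$tp, cats$tn) else NULL
      data.frame(drug_id = d, n_tp = length(cats$tp), n_tn = length(cats$tn),
                 n_significant = if (is.null(cmp)) NA_integer_
                 else sum(cmp$significant), stringsAsFactors = FALSE)
    })
    list(top_pathways = top, per_drug = do.call(rbind, per_drug))
  })
  report$explain <- list(top_pathways = expl$top_pathways,
                         per_drug = expl$per_drug)
  utils::write.table(expl$per_drug,
                     file.path(out_dir, "group_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(report)
}

#' Built-in demo configuration
#'
#' A small cohort that exercises every stage in a couple of minutes on one
#' CPU.
#'
#' @param seed global seed.
#' @return `pipeline_config`.
#' @export
demo_config <- function(seed = 1) {
  pipeline_config(
    seed = seed,
    sim = sim_config(n_cell_samples = 1000, n_tumor_samples = 80,
                     n_batches = 2, n_drugs = 5, effect_size = 1.5,
                     noise_sd = 0.5, seed = seed),
    drug = list(n_perm = 30),
    pretrain = list(max_epochs = 60),
    transfer = list(max_epochs = 60),
    evaluate = list(k = 5, repeats = 2),
    explain = list(n_perm = 2, n_baseline = 20))
}

#' Run the demo pipeline
#' @param seed global seed.
#' @param out_dir run directory.
#' @return report, invisibly.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("pathdrp_demo_")) {
  run_pipeline(demo_config(seed), out_dir)
}
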