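# The feed-forward sensitivity network: construction, training contracts
# (clipping, early stopping, determinism), prediction and persistence.

test_that("parameter counts follow the layer chain", {
  m <- build_network(10, "regression", widths = c(4, 3))
  expect_equal(n_params(m), 10 * 4 + 4 + 4 * 3 + 3 + 3 * 1 + 1)
  expect_error(build_network(10, widths = c(0)), "width")
  expect_error(build_network(0, widths = c(4)), "input_dim")
})

test_that("classification outputs are probabilities", {
  m <- build_network(5, "classification", widths = c(4))
  p <- predict(m, matrix(rnorm(50), 10, 5))
  expect_true(all(p > 0 & p < 1))
})

test_that("zero-weight models predict the output bias", {
  m <- build_network(3, "regression", widths = c(2))
  m$layers <- lapply(m$layers, function(l) { l$W[] <- 0; l$b[] <- 0; l })
  m$layers[[2]]$b <- 0.7
  expect_equal(predict(m, matrix(rnorm(12), 4, 3)), rep(0.7, 4))
  mc <- build_network(3, "classification", widths = c(2))
  mc$layers <- lapply(mc$layers, function(l) { l$W[] <- 0; l$b[] <- 0; l })
  expect_equal(predict(mc, matrix(rnorm(6), 2, 3)), rep(0.5, 2))
})

test_that("training is deterministic under a fixed seed", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  y <- X %*% c(1, -1, 0.5, 0) + rnorm(50, sd = 0.1)
  cfg <- train_config(loss = "mse", max_epochs = 10, batch_size = 16, seed = 5)
  m1 <- fit_network(build_network(4, "regression", c(6), seed = 2), X, y, cfg)
  m2 <- fit_network(build_network(4, "regression", c(6), seed = 2), X, y, cfg)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$log, m2$log)
})

test_that("weights stay inside the clip range during aggressive training", {
  set.seed(2)
  X <- matrix(rnorm(400), 100, 4)
  y <- 100 * X[, 1]
  cfg <- train_config(loss = "mse", learning_rate = 1, max_epochs = 15,
                      clip_range = c(-5, 5), batch_size = 25, seed = 6)
  m <- fit_network(build_network(4, "regression", c(5), seed = 3), X, y, cfg)
  for (l in m$layers) {
    expect_lte(max(abs(l$W)), 5)
    expect_lte(max(abs(l$b)), 5)
  }
})

test_that("early stopping restores the best validation epoch", {
  set.seed(3)
  X <- matrix(rnorm(600), 150, 4)
  y <- X[, 1] - X[, 2] + rnorm(150, sd = 0.3)
  cfg <- train_config(loss = "mse", learning_rate = 5e-3, patience = 5,
                      max_epochs = 100, batch_size = 32, seed = 7)
  m <- fit_network(build_network(4, "regression", c(8), seed = 4), X, y, cfg)
  best <- m$best_epoch
  expect_true(best >= 1)
  later <- m$log$val_loss[m$log$epoch > best]
  expect_true(all(m$log$val_loss[best] <= later + 1e-12))
  # at most patience epochs after the best one
  expect_lte(nrow(m$log) - best, cfg$patience)
})

test_that("a clean nonlinear response is fit to low error", {
  co <- generate_cohort(sim_config(n_genes = 80, n_pathways = 8,
                                   n_cell_samples = 300, n_tumor_samples = 20,
                                   n_drugs = 3, noise_sd = 0,
                                   batch_shift_sd = 0,
                                   batch_scale_range = c(1, 1), seed = 17))
  ch <- chem_matrix(co$drugs)
  dg <- dgnet_matrix(co$ppi, co$drugs, co$gene_sets, n_perm = 20, seed = 1)
  r <- co$resp_cells_cont
  X <- cbind(co$truth$activity[r$sample_id, ], ch[r$drug_id, ], dg[r$drug_id, ])
  cfg <- train_config(loss = "rmse", learning_rate = 5e-3, max_epochs = 300,
                      patience = 60, seed = 8)
  m <- fit_network(build_network(ncol(X), "regression", c(32, 16), seed = 9),
                   X, r$response, cfg)
  expect_lt(tail(m$log$train_loss, 1), 0.05)
})

test_that("shuffled labels yield no learning beyond the label spread", {
  set.seed(4)
  co <- generate_cohort(sim_config(n_genes = 60, n_pathways = 6,
                                   n_cell_samples = 150, n_tumor_samples = 20,
                                   n_drugs = 2, noise_sd = 0.3, seed = 19))
  ch <- chem_matrix(co$drugs)
  dg <- dgnet_matrix(co$ppi, co$drugs, co$gene_sets, n_perm = 20, seed = 1)
  r <- co$resp_cells_cont
  X <- cbind(co$truth$activity[r$sample_id, ], ch[r$drug_id, ], dg[r$drug_id, ])
  y <- sample(r$response)
  cfg <- train_config(loss = "rmse", learning_rate = 1e-3, max_epochs = 60,
                      seed = 10)
  m <- fit_network(build_network(ncol(X), "regression", c(16, 8), seed = 11),
                   X, y, cfg)
  expect_equal(min(m$log$val_loss, na.rm = TRUE), sd(y), tolerance = 0.1)
})

test_that("pretrain can target either sensitivity scale and records a log", {
  co <- small_cohort()
  h <- harmonize_run(list(co$cells, co$tumors))
  s <- ssgsea_matrix(h, co$gene_sets)
  ch <- chem_matrix(co$drugs)
  dg <- dgnet_matrix(co$ppi, co$drugs, co$gene_sets, n_perm = 20, seed = 1)
  fc <- build_feature_table(s, ch, dg, co$resp_cells_cont)
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 15, seed = 12)
  m_auc <- pretrain(fc, cfg, widths = c(16, 8))
  m_ic50 <- pretrain(fc, cfg, widths = c(16, 8), target = "neg_log10_ic50")
  expect_s3_class(m_auc, "sensitivity_model")
  expect_true(all(m_auc$provenance$pretrained))
  expect_false(identical(m_auc$layers, m_ic50$layers))
  # losses live on different response scales; both logs must be recorded
  expect_gt(nrow(m_auc$log), 0)
  expect_gt(nrow(m_ic50$log), 0)
})

test_that("models survive a save/load round trip and reject corrupt files", {
  m <- build_network(6, "classification", c(5, 3), seed = 13)
  X <- matrix(rnorm(60), 10, 6)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m, X), predict(m2, X))
  expect_identical(m$layers, m2$layers)

  writeLines("{\"version\": \"other-format\"}", f)
  expect_error(load_model(f), "version")
  writeLines("not json at all {", f)
  expect_error(load_model(f), "parse")
})

test_that("prediction validates the feature dimension", {
  m <- build_network(4, "regression", c(3))
  expect_error(predict(m, matrix(0, 2, 5)), "dimension mismatch")
})
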