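# Layer transfer, freezing, imbalance subsampling and hyperparameter search.

make_pretrained <- function(input_dim = 12, widths = c(8, 6)) {
  m <- build_network(input_dim, "regression", widths, seed = 1)
  m$provenance$pretrained <- TRUE
  m
}

test_that("transfer_build copies, freezes, and validates depth", {
  pre <- make_pretrained()
  cfg <- transfer_config(n_transfer_layers = 2, retrain_transferred = FALSE,
                         head = "classification", seed = 2)
  m <- transfer_build(pre, cfg)
  expect_identical(m$layers[[1]], pre$layers[[1]])
  expect_identical(m$layers[[2]], pre$layers[[2]])
  expect_true(all(m$provenance$frozen[1:2]))
  expect_false(m$provenance$frozen[3])
  expect_equal(m$head, "classification")

  m0 <- transfer_build(pre, transfer_config(n_transfer_layers = 0,
                                            new_hidden_layers = c(4),
                                            head = "classification"))
  expect_false(any(m0$provenance$pretrained))

  expect_error(transfer_build(pre, transfer_config(n_transfer_layers = 5)),
               "0..2")
})

test_that("frozen layers are bitwise unchanged by fine-tuning", {
  set.seed(3)
  pre <- make_pretrained()
  n <- 80
  x <- matrix(rnorm(n * 12), n, 12)
  y <- as.numeric(runif(n) < plogis(x[, 1]))
  ft <- list(x = x, y = y, sample_id = paste0("s", 1:n),
             drug_id = rep("d1", n), kind = "dichotomous",
             blocks = list(), extra = list())
  class(ft) <- "feature_table"
  cfg <- transfer_config(n_transfer_layers = 2, retrain_transferred = FALSE,
                         head = "classification",
                         train = train_config(loss = "bce", max_epochs = 100,
                                              patience = 100, batch_size = 16,
                                              val_fraction = 0.2, seed = 4))
  m <- fine_tune(transfer_build(pre, cfg), ft, cfg)
  expect_identical(m$layers[[1]], pre$layers[[1]])
  expect_identical(m$layers[[2]], pre$layers[[2]])
  # the head did train
  init <- transfer_build(pre, cfg)
  expect_false(identical(m$layers[[3]], init$layers[[3]]))
  expect_equal(m$updated_layers, 3)
})

test_that("retrainable transfer really updates the transferred layers", {
  set.seed(5)
  pre <- make_pretrained()
  n <- 60
  x <- matrix(rnorm(n * 12), n, 12)
  ft <- list(x = x, y = as.numeric(runif(n) < 0.5), sample_id = paste0("s", 1:n),
             drug_id = rep("d1", n), kind = "dichotomous",
             blocks = list(), extra = list())
  class(ft) <- "feature_table"
  cfg <- transfer_config(n_transfer_layers = 2, retrain_transferred = TRUE,
                         head = "classification",
                         train = train_config(loss = "bce", max_epochs = 20,
                                              batch_size = 16,
                                              val_fraction = 0.2, seed = 6))
  m <- fine_tune(transfer_build(pre, cfg), ft, cfg)
  expect_false(identical(m$layers[[1]], pre$layers[[1]]))
})

test_that("non-responder subsampling hits the requested per-drug ratio", {
  tab <- response_table(
    sprintf("s%03d", 1:90),
    rep(c("dA", "dB"), c(45, 45)),
    c(rep(1, 5), rep(0, 40), rep(1, 5), rep(0, 10), rep(0, 30)),
    kind = "dichotomous")
  # dA: 5 responders, 40 non; dB: 5 responders, 40 non but we cap below
  out <- subsample_nonresponders(tab, ratio = 3, seed = 7)
  for (d in c("dA", "dB")) {
    nr <- sum(out$drug_id == d & out$response == 1)
    nn <- sum(out$drug_id == d & out$response == 0)
    expect_equal(nr, 5)
    expect_equal(nn, 15)
  }
  expect_no_dup_rows(out)
  # all responders kept
  expect_true(all(tab$sample_id[tab$response == 1] %in%
                    out$sample_id[out$response == 1]))

  few <- response_table(sprintf("t%02d", 1:15), rep("dC", 15),
                        c(rep(1, 5), rep(0, 10)), kind = "dichotomous")
  out2 <- subsample_nonresponders(few, ratio = 3)
  expect_equal(nrow(out2), 15)   # only 10 non-responders exist: cap

  none <- response_table(sprintf("u%02d", 1:6), rep("dD", 6), rep(0, 6),
                         kind = "dichotomous")
  expect_warning(out3 <- subsample_nonresponders(none, ratio = 3),
                 "no responders")
  expect_equal(nrow(out3), 0)
  expect_error(subsample_nonresponders(few, ratio = 0), "ratio")
  expect_identical(subsample_nonresponders(tab, 3, seed = 8),
                   subsample_nonresponders(tab, 3, seed = 8))
})

test_that("the sequential search recovers a planted unimodal optimum", {
  space <- list(list(name = "learning_rate", type = "loguniform",
                     bounds = c(1e-4, 1e-1)),
                list(name = "dropout", type = "uniform", bounds = c(0, 0.5)))
  target <- function(pt) -(log10(pt$learning_rate) + 2.5)^2 - (pt$dropout - 0.2)^2
  r <- hyperparameter_search(NULL, NULL, space, budget = 20, seed = 3,
                             objective = target)
  expect_equal(nrow(r$trace), 20)
  # best found within the top decile of the response surface:
  # optimum is 0, the surface over the box spans down to ~ -2.6
  expect_gt(r$best$objective, -0.26)

  r2 <- hyperparameter_search(NULL, NULL, space, budget = 20, seed = 3,
                              objective = target)
  expect_identical(r$trace, r2$trace)

  r1 <- hyperparameter_search(NULL, NULL, space, budget = 1, seed = 4,
                              objective = target)
  expect_equal(nrow(r1$trace), 1)
  expect_error(hyperparameter_search(NULL, NULL, list(), budget = 2,
                                     objective = target), "empty")
  expect_error(hyperparameter_search(NULL, NULL, space, budget = 0,
                                     objective = target), "budget")
})

test_that("the inner-CV objective evaluates a real configuration end to end", {
  co <- small_cohort()
  h <- harmonize_run(list(co$cells, co$tumors))
  s <- ssgsea_matrix(h, co$gene_sets)
  ch <- chem_matrix(co$drugs)
  dg <- dgnet_matrix(co$ppi, co$drugs, co$gene_sets, n_perm = 20, seed = 1)
  fc <- build_feature_table(s, ch, dg, co$resp_cells_cont)
  ft <- build_feature_table(s, ch, dg, co$resp_tumors_dich)
  pre <- pretrain(fc, train_config(learning_rate = 1e-3, max_epochs = 15,
                                   seed = 2), widths = c(16, 8))
  space <- list(list(name = "n_transfer_layers", type = "choice", values = 0:2),
                list(name = "learning_rate", type = "loguniform",
                     bounds = c(1e-4, 1e-2)))
  r <- hyperparameter_search(pre, ft, space, budget = 2, seed = 5)
  expect_equal(nrow(r$trace), 2)
  expect_true(all(is.finite(r$trace$objective)))
  expect_true(r$best$objective >= max(r$trace$objective) - 1e-12)
})
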