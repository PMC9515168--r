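# Metrics and repeated cross-validation.

test_that("auroc matches hand-enumerable cases", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 0.75)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("auroc equals pairwise concordance on random instances", {
  set.seed(10)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(round(rnorm(n), 1))   # rounded: force some ties
    expect_equal(auroc(labels, scores), oracle_auroc(labels, scores))
  }
})

test_that("auroc flips under score negation for tie-free scores", {
  set.seed(11)
  labels <- rep(c(0, 1), 10)
  scores <- rnorm(20)
  expect_equal(auroc(labels, scores), 1 - auroc(labels, -scores))
})

test_that("rmse matches hand arithmetic", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("model comparison is the exact Mann-Whitney test on small samples", {
  expect_equal(compare_models(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(compare_models(c(1, 2, 3), c(3, 2, 1)), 1.0)
  a <- c(0.7, 0.8, 0.6, 0.75); b <- c(0.5, 0.55, 0.65, 0.45)
  expect_equal(compare_models(a, b), compare_models(rev(a), rev(b)))
  expect_error(compare_models(c(1, 2), c(3, 4, 5)), ">= 3")
})

test_that("repeated CV returns k x repeats folds and is seed-stable", {
  co <- small_cohort()
  n <- 200
  ft <- list(x = matrix(rnorm(n * 3), n, 3), y = rbinom(n, 1, 0.5),
             sample_id = paste0("s", 1:n),
             drug_id = rep(c("d1", "d2"), n / 2), kind = "dichotomous",
             cancer_type = rep("BRCA", n), blocks = list(), extra = list())
  class(ft) <- "feature_table"
  oracle_fit <- function(tr) tr      # "model" = memorize nothing
  oracle_pred <- function(model, x) x[, 1]
  r <- repeated_cv(ft, oracle_fit, oracle_pred, metric = "auroc",
                   k = 5, repeats = 5, seed = 3)
  expect_length(r$fold_scores, 25)
  expect_equal(nrow(r$predictions), 25 / 5 * n)
  r2 <- repeated_cv(ft, oracle_fit, oracle_pred, metric = "auroc",
                    k = 5, repeats = 5, seed = 3)
  expect_identical(r$fold_scores, r2$fold_scores)

  # a perfect-oracle pipeline scores 1 in every fold
  ft$y <- as.numeric(ft$x[, 1] > 0)
  perfect <- repeated_cv(ft, oracle_fit, oracle_pred, metric = "auroc",
                         k = 5, repeats = 2, seed = 4)
  expect_true(all(perfect$fold_scores == 1))
})

test_that("fold means are stable across reseeding", {
  set.seed(12)
  n <- 300
  x <- matrix(rnorm(n * 2), n, 2)
  y <- as.numeric(runif(n) < plogis(2 * x[, 1]))
  ft <- list(x = x, y = y, sample_id = paste0("s", 1:n),
             drug_id = rep("d", n), kind = "dichotomous",
             cancer_type = NULL, blocks = list(), extra = list())
  class(ft) <- "feature_table"
  fit <- function(tr) glm.fit(cbind(1, tr$x), tr$y)
  prd <- function(m, x) as.numeric(cbind(1, x) %*% m$coefficients)
  r1 <- repeated_cv(ft, fit, prd, metric = "auroc", seed = 1)
  r2 <- repeated_cv(ft, fit, prd, metric = "auroc", seed = 2)
  se <- sqrt(r1$sd^2 / 25 + r2$sd^2 / 25)
  expect_lt(abs(r1$mean - r2$mean), 2 * se + 0.02)
})

test_that("per-group breakdown excludes small or single-class groups", {
  preds <- data.frame(
    sample_id = paste0("s", 1:14),
    drug_id = c(rep("big", 10), rep("small", 4)),
    cancer_type = "BRCA",
    y = c(rep(c(0, 1), 5), 1, 1, 0, 0),
    pred = c(seq(0.1, 1, 0.1), 0.9, 0.8, 0.2, 0.1),
    rep = 1, fold = 1)
  out <- per_group_performance(preds, "drug_id",
                               membership = c(big = TRUE, small = TRUE),
                               min_group_n = 5, metric = "auroc")
  expect_equal(out$table$group, "big")
  expect_equal(out$member_mean, out$table$value)
  expect_true(is.na(out$nonmember_mean))

  # single-class group excluded with warning
  preds2 <- preds
  preds2$y[preds2$drug_id == "big"] <- 1
  preds2$y[preds2$drug_id == "small"] <- c(1, 1, 0, 0)
  expect_warning(
    out2 <- per_group_performance(preds2, "drug_id", min_group_n = 4,
                                  metric = "auroc"),
    "single class")
  expect_equal(out2$table$group, "small")
})
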