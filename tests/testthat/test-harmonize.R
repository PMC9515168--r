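# 3-step harmonization: gene intersection, gene-wise standardization,
# empirical-Bayes location/scale batch adjustment.

test_that("intersect_genes restricts to the sorted common gene set", {
  m1 <- toy_expr(matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2"))))
  m2 <- toy_expr(matrix(1:6, 3, 2, dimnames = list(c("B", "C", "D"), c("t1", "t2"))))
  out <- intersect_genes(list(m1, m2))
  expect_equal(rownames(out[[1]]$values), c("B", "C"))
  expect_equal(rownames(out[[2]]$values), c("B", "C"))

  same <- intersect_genes(list(m1, m1))
  expect_equal(rownames(same[[1]]$values), sort(rownames(m1$values)))

  m3 <- toy_expr(matrix(1:4, 2, 2, dimnames = list(c("X", "Y"), c("u1", "u2"))))
  expect_error(intersect_genes(list(m1, m3)), "empty")
})

test_that("gene-wise standardization yields mean 0 / sd 1 and drops constants", {
  m <- toy_expr(matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
                       dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
  expect_warning(std <- standardize_genewise(m), "zero-variance")
  expect_equal(unname(std$matrix$values["g1", ]), c(-1, 0, 1))
  expect_false("g2" %in% rownames(std$matrix$values))

  # idempotence: standardizing a standardized matrix changes nothing
  again <- standardize_genewise(std$matrix)
  expect_equal(again$matrix$values, std$matrix$values, tolerance = 1e-10)

  all_const <- toy_expr(matrix(1, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z"))))
  expect_error(standardize_genewise(all_const), "zero variance")
})

test_that("fit_combat validates batch structure", {
  m <- toy_expr(matrix(rnorm(20), 4, 5,
                       dimnames = list(paste0("g", 1:4), paste0("s", 1:5))),
                batch = "only")
  expect_error(fit_combat(m), "2 batches")
  m2 <- toy_expr(matrix(rnorm(16), 4, 4,
                        dimnames = list(paste0("g", 1:4), paste0("s", 1:4))),
                 batch = c("a", "a", "a", "b"))
  expect_error(fit_combat(m2), "single sample.*b")
})

test_that("EB estimates match a hand-computed method-of-moments oracle on a toy", {
  # 2 batches x 2 samples, 3 genes; oracle implements the estimator formulas
  # directly (no iteration needed to first order: start from the raw
  # estimates and iterate the two conditional equations)
  set.seed(7)
  z <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  z <- t(scale(t(z)))  # standardized input
  m <- toy_expr(z, batch = c("A", "A", "B", "B"))
  model <- fit_combat(m)

  for (b in c("A", "B")) {
    j <- m$batch == b
    gh <- rowMeans(z[, j]); dh <- apply(z[, j], 1, var)
    gbar <- mean(gh); tau2 <- var(gh)
    V <- mean(dh); S2 <- var(dh)
    lam <- (2 * S2 + V^2) / S2
    th <- (V * S2 + V^3) / S2
    g <- gh; d <- dh; n <- sum(j)
    for (it in 1:200) {
      g_new <- (n * tau2 * gh + d * gbar) / (n * tau2 + d)
      d_new <- (th + 0.5 * rowSums((z[, j] - g_new)^2)) / (n / 2 + lam - 1)
      if (max(abs(g_new - g), abs(d_new - d)) < 1e-10) break
      g <- g_new; d <- d_new
    }
    expect_equal(unname(model$gamma_star[, b]), unname(g), tolerance = 1e-3)
    expect_equal(unname(model$delta_star[, b]), unname(d), tolerance = 1e-3)
    expect_true(all(model$delta_star[, b] > 0))
  }
})

test_that("zero planted effects give gamma* near 0 and delta* near 1", {
  set.seed(21)
  n <- 500; G <- 60
  z <- matrix(rnorm(G * 2 * n), G, 2 * n,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("s%04d", 1:(2 * n))))
  z <- t(scale(t(z)))
  m <- toy_expr(z, batch = rep(c("A", "B"), each = n))
  model <- fit_combat(m)
  expect_lt(mean(abs(model$gamma_star)), 0.1)
  expect_lt(max(abs(model$delta_star - 1)), 0.3)
})

test_that("a planted additive shift is recovered within 10%", {
  set.seed(22)
  n <- 500; G <- 50
  raw <- matrix(rnorm(G * 2 * n, mean = 5), G, 2 * n,
                dimnames = list(sprintf("g%02d", 1:G), sprintf("s%04d", 1:(2 * n))))
  raw[, (n + 1):(2 * n)] <- raw[, (n + 1):(2 * n)] + 2   # shift batch B
  m <- toy_expr(raw, batch = rep(c("A", "B"), each = n))
  std <- standardize_genewise(m)
  model <- fit_combat(std$matrix)
  # on the original scale, gamma* differences must recover the +2 shift
  recovered <- (model$gamma_star[, "B"] - model$gamma_star[, "A"]) * std$scale
  expect_equal(mean(recovered), 2, tolerance = 0.2)
})

test_that("apply_combat equalizes batch means and is ~identity on clean data", {
  set.seed(23)
  n <- 500; G <- 40
  z <- matrix(rnorm(G * 2 * n), G, 2 * n,
              dimnames = list(sprintf("g%02d", 1:G), sprintf("s%04d", 1:(2 * n))))
  z <- t(scale(t(z)))
  m <- toy_expr(z, batch = rep(c("A", "B"), each = n))
  adj <- apply_combat(m, fit_combat(m))
  expect_lt(max(abs(adj$values - m$values)), 0.25)
  expect_lt(mean(abs(adj$values - m$values)), 0.05)

  shifted <- m
  shifted$values[, (n + 1):(2 * n)] <- shifted$values[, (n + 1):(2 * n)] + 2
  adj2 <- apply_combat(shifted, fit_combat(shifted))
  gapA <- rowMeans(adj2$values[, 1:n]) - rowMeans(adj2$values[, (n + 1):(2 * n)])
  expect_lt(mean(abs(gapA)), 0.05)

  bad <- m; bad$batch[1] <- "C"
  expect_error(apply_combat(bad, fit_combat(m)), "unknown batch")
})

test_that("harmonize_run removes planted effects without destroying signal", {
  co <- small_cohort()
  joint <- harmonize_run(list(co$cells, co$tumors))

  # ~95% of genes: between-batch mean difference within 3 SE of 0
  b <- joint$batch
  bl <- unique(b)
  ok <- vapply(seq_len(nrow(joint$values)), function(g) {
    v1 <- joint$values[g, b == bl[1]]; v2 <- joint$values[g, b == bl[2]]
    se <- sqrt(var(v1) / length(v1) + var(v2) / length(v2))
    abs(mean(v1) - mean(v2)) < 3 * se
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  # signal preservation: pathway-activity correlation of mean member-gene
  # expression drops < 10% relative to the unadjusted standardized data
  act <- co$truth$activity
  std <- standardize_genewise(expression_matrix(
    cbind(co$cells$values, co$tumors$values),
    batch = c(co$cells$batch, co$tumors$batch),
    cancer_type = c(co$cells$cancer_type, co$tumors$cancer_type)))$matrix
  cor_for <- function(m) {
    mean(vapply(names(co$gene_sets), function(p) {
      g <- intersect(co$gene_sets[[p]], rownames(m$values))
      cor(colMeans(m$values[g, , drop = FALSE]), act[colnames(m$values), p])
    }, numeric(1)))
  }
  expect_gt(cor_for(joint), 0.9 * cor_for(std))
})

test_that("harmonize_run agrees with the reference EB batch correction", {
  co <- small_cohort()
  joint <- harmonize_run(list(co$cells, co$tumors))
  std <- standardize_genewise(expression_matrix(
    cbind(co$cells$values, co$tumors$values),
    batch = c(co$cells$batch, co$tumors$batch),
    cancer_type = c(co$cells$cancer_type, co$tumors$cancer_type)))$matrix
  ref <- sva::ComBat(std$values, batch = std$batch)
  expect_gt(cor(as.numeric(joint$values), as.numeric(ref[rownames(joint$values), ])),
            0.98)
})

test_that("harmonize_run is approximately idempotent on zero-effect data", {
  co <- generate_cohort(sim_config(n_genes = 60, n_pathways = 6,
                                   n_cell_samples = 60, n_tumor_samples = 40,
                                   batch_shift_sd = 0,
                                   batch_scale_range = c(1, 1), seed = 31))
  once <- harmonize_run(list(co$cells, co$tumors))
  twice <- harmonize_run(list(expression_matrix(once$values, once$batch,
                                                once$cancer_type)))
  # the residual re-adjustment is bounded by the sampling error of the
  # per-batch estimates at this cohort size
  expect_lt(mean(abs(twice$values - once$values)), 0.02)
  expect_lt(max(abs(twice$values - once$values)), 0.15)
})
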