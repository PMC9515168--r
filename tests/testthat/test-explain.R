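# Shapley attributions (axioms), importance ranking, TP/TN categorization
# and group comparison with FDR control.

test_that("linear models get exact attributions phi_i = w_i (x_i - b_i)", {
  w <- c(2, -1, 0.5, 3)
  f <- function(X) as.numeric(X %*% w)
  x <- matrix(c(1, 2, 3, 4), 1)
  b <- matrix(c(0.5, 0, -1, 2), 1)
  att <- shapley_values(f, x, b, n_perm = 3, seed = 1, exact_max = 0)
  expect_equal(as.numeric(att$values), as.numeric(w * (x - b)),
               tolerance = 1e-10)
  # exact path agrees
  att2 <- shapley_values(f, x, b, seed = 1, exact_max = 12)
  expect_equal(att$values, att2$values, tolerance = 1e-10)
})

test_that("a two-feature product model splits credit symmetrically", {
  f <- function(X) X[, 1] * X[, 2]
  att <- shapley_values(f, matrix(c(1, 1), 1), matrix(c(0, 0), 1), seed = 2)
  expect_equal(as.numeric(att$values), c(0.5, 0.5))
})

test_that("constant models and ignored features get zero attribution", {
  att <- shapley_values(function(X) rep(4, nrow(X)),
                        matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3),
                        seed = 3)
  expect_true(all(abs(att$values) < 1e-12))

  # a network with zeroed input weights for feature 1 is provably blind to it
  m <- build_network(4, "regression", c(5, 3), seed = 4)
  m$layers[[1]]$W[1, ] <- 0
  att2 <- shapley_values(m, matrix(rnorm(20), 5, 4), matrix(rnorm(12), 3, 4),
                         n_perm = 4, seed = 5, exact_max = 0)
  expect_lt(max(abs(att2$values[, 1])), 1e-6)
})

test_that("sampled attributions satisfy efficiency exactly per baseline mean", {
  m <- build_network(6, "regression", c(8, 4), seed = 6)
  f <- function(X) predict(m, X)
  x <- matrix(rnorm(30), 5, 6)
  b <- matrix(rnorm(24), 4, 6)
  att <- shapley_values(f, x, b, n_perm = 3, seed = 7, exact_max = 0)
  for (i in 1:5) {
    expect_equal(sum(att$values[i, ]), f(x)[i] - mean(f(b)), tolerance = 1e-10)
  }
})

test_that("exchangeable features receive equal attribution", {
  f <- function(X) X[, 1] + X[, 2]
  att <- shapley_values(f, matrix(c(2, 2, 1), 1), matrix(c(0, 0, 0), 1),
                        seed = 8)
  expect_equal(att$values[1, 1], att$values[1, 2], tolerance = 1e-10)
})

test_that("importance ranking orders by mean |phi| with lexicographic ties", {
  att <- structure(list(values = matrix(c(0, 0, 0, 0), 2,
                                        dimnames = list(NULL, c("b", "a"))),
                        importance = c(b = 0, a = 0)),
                   class = "attribution")
  r <- rank_importance(att)
  expect_equal(r$feature, c("a", "b"))
  expect_equal(nrow(rank_importance(att, top_k = 0)), 0)
  expect_warning(r2 <- rank_importance(att, top_k = 10), "truncated")
  expect_equal(nrow(r2), 2)
})

test_that("prediction categorization follows the >= threshold convention", {
  labs <- c(1, 0, 1, 0)
  out <- categorize_predictions(labs, probs = labs, ids = letters[1:4])
  expect_equal(out$tp, c("a", "c"))
  expect_equal(out$tn, c("b", "d"))

  none <- suppressWarnings(categorize_predictions(labs, probs = 1 - labs,
                                                  ids = letters[1:4]))
  expect_length(none$tp, 0)
  expect_length(none$tn, 0)

  edge <- suppressWarnings(categorize_predictions(c(1, 0), c(0.5, 0.5),
                                                  ids = c("x", "y")))
  expect_equal(edge$tp, "x")   # prob exactly at threshold counts positive
  expect_length(suppressWarnings(categorize_predictions(c(1, 0), c(0.5, 0.5),
                                                        ids = c("x", "y"))$tn), 0)
})

test_that("group comparison applies BH step-up and flags at q < alpha", {
  # construct scores whose per-pathway MWU p-values are known to be small
  set.seed(9)
  ga <- paste0("a", 1:6); gb <- paste0("b", 1:6)
  scores <- rbind(matrix(rnorm(6 * 4, mean = 3), 6, 4),
                  matrix(rnorm(6 * 4, mean = 0), 6, 4))
  rownames(scores) <- c(ga, gb)
  colnames(scores) <- paste0("PW", 1:4)
  cmp <- compare_groups(scores, ga, gb, alpha = 0.05)
  expect_equal(cmp$q, p.adjust(cmp$p, "BH"))
  expect_true(all(cmp$q >= cmp$p))
  expect_true(any(cmp$significant))

  expect_error(compare_groups(scores, ga, c(ga[1], gb[1:3])), "overlap")
  expect_error(compare_groups(scores, ga[1:2], gb), ">= 3")
})

test_that("null group comparisons rarely flag pathways", {
  set.seed(10)
  hits <- replicate(20, {
    scores <- matrix(rnorm(12 * 8), 12, 8,
                     dimnames = list(paste0("s", 1:12), paste0("PW", 1:8)))
    cmp <- compare_groups(scores, paste0("s", 1:6), paste0("s", 7:12))
    sum(cmp$significant)
  })
  expect_lt(mean(hits > 0), 0.2)
})
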