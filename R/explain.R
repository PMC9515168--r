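# Shapley-value attribution of model predictions to input features, feature
# importance ranking, prediction-outcome categorization (true positives /
# true negatives) and responder-vs-non-responder pathway comparison with
# Benjamini-Hochberg FDR control.

as_predictor <- function(model) {
  if (is.function(model)) model
  else if (inherits(model, "sensitivity_model")) function(X) predict(model, X)
  else stop2("model must be a function or a sensitivity_model")
}

#' Shapley feature attributions
#'
#' Exact subset-enumeration Shapley values when the feature count is at most
#' `exact_max`; otherwise a permutation-sampling estimate in which every
#' baseline row is used once per sampled permutation, making the efficiency
#' identity (attributions sum to f(x) minus the mean baseline prediction)
#' hold exactly.
#'
#' @param model a `sensitivity_model` or a function(matrix) -> numeric.
#' @param x matrix of samples to explain (rows).
#' @param baseline non-empty matrix of reference rows (e.g. 100 seeded
#'   training rows).
#' @param n_perm sampled permutations per sample (ignored on the exact path).
#' @param seed RNG seed.
#' @param exact_max exact enumeration threshold on the feature count.
#' @return an `attribution` object: `values` (samples x features),
#'   `importance` (mean |value| per feature), `baseline_mean` prediction.
#' @export
shapley_values <- function(model, x, baseline, n_perm = 8, seed = 1,
                           exact_max = 12) {
  f <- as_predictor(model)
  x <- as.matrix(x); baseline <- as.matrix(baseline)
  if (nrow(baseline) == 0) stop2("baseline set must be non-empty")
  if (ncol(x) != ncol(baseline)) stop2("feature dimension mismatch")
  d <- ncol(x)
  phi <- with_seed(seed, {
    if (d <= exact_max) shapley_exact(f, x, baseline)
    else shapley_sampled(f, x, baseline, n_perm)
  })
  colnames(phi) <- colnames(x)
  rownames(phi) <- rownames(x)
  structure(list(values = phi,
                 importance = colMeans(abs(phi)),
                 baseline_mean = mean(f(baseline)),
                 n_baseline = nrow(baseline)),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("attribution: %d samples x %d features (baseline n = %d)\n",
              nrow(x$values), ncol(x$values), x$n_baseline))
  invisible(x)
}

shapley_exact <- function(f, x, baseline) {
  d <- ncol(x)
  n_masks <- 2^d
  masks <- base::matrix(FALSE, n_masks, d)
  for (i in seq_len(d)) masks[, i] <- bitwAnd(0:(n_masks - 1), bitwShiftL(1L, i - 1L)) > 0
  sizes <- rowSums(masks)
  # |S|! (d-|S|-1)! / d!  for the subset S a feature joins
  wts <- exp(lgamma(sizes + 1) + lgamma(d - sizes) - lgamma(d + 1))
  phi <- base::matrix(0, nrow(x), d)
  for (s in seq_len(nrow(x))) {
    v <- numeric(n_masks)
    for (b in seq_len(nrow(baseline))) {
      X <- base::matrix(baseline[b, ], n_masks, d, byrow = TRUE)
      X[masks] <- base::matrix(x[s, ], n_masks, d, byrow = TRUE)[masks]
      v <- v + f(X)
    }
    v <- v / nrow(baseline)
    for (i in seq_len(d)) {
      without <- !masks[, i]
      with_i <- which(without) + 2^(i - 1)
      phi[s, i] <- sum(wts[without] * (v[with_i] - v[without]))
    }
  }
  phi
}

shapley_sampled <- function(f, x, baseline, n_perm) {
  d <- ncol(x)
  nb <- nrow(baseline)
  phi <- base::matrix(0, nrow(x), d)
  for (s in seq_len(nrow(x))) {
    for (p in seq_len(n_perm)) {
      ord <- sample(d)
      # rows 1..(d+1) per baseline: baseline, then features revealed in order
      big <- base::matrix(0, (d + 1) * nb, d)
      for (b in seq_len(nb)) {
        mat <- base::matrix(baseline[b, ], d + 1, d, byrow = TRUE)
        for (j in seq_len(d)) mat[(j + 1):(d + 1), ord[j]] <- x[s, ord[j]]
        big[((b - 1) * (d + 1) + 1):(b * (d + 1)), ] <- mat
      }
      pred <- f(big)
      for (b in seq_len(nb)) {
        off <- (b - 1) * (d + 1)
        phi[s, ord] <- phi[s, ord] + diff(pred[(off + 1):(off + d + 1)])
      }
    }
    phi[s, ] <- phi[s, ] / (n_perm * nb)
  }
  phi
}

#' Rank features by Shapley importance
#'
#' @param att an `attribution`.
#' @param top_k how many features to return (all if NULL); values beyond the
#'   feature count are truncated with a warning.
#' @param features optional subset of feature names or column indices to
#'   rank within (e.g. the EXP block).
#' @return data.frame(feature, importance), importance descending, ties
#'   broken lexicographically.
#' @export
rank_importance <- function(att, top_k = NULL, features = NULL) {
  imp <- att$importance
  if (!is.null(features)) imp <- imp[features]
  if (length(imp) == 0) stop2("empty attribution")
  nm <- names(imp) %||% as.character(seq_along(imp))
  ord <- order(-imp, nm)
  out <- data.frame(feature = nm[ord], importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) {
    if (top_k > nrow(out)) {
      warning("top_k exceeds feature count; truncated to ", nrow(out))
      top_k <- nrow(out)
    }
    out <- out[seq_len(top_k), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Categorize predictions into true positives and true negatives
#'
#' @param labels 0/1 vector.
#' @param probs predicted probabilities.
#' @param threshold classification threshold (prob >= threshold is called
#'   positive).
#' @param ids per-row identifiers (row indices by default).
#' @return list with `tp` and `tn` id vectors.
#' @export
categorize_predictions <- function(labels, probs, threshold = 0.5,
                                   ids = seq_along(labels)) {
  if (!all(labels %in% c(0, 1))) stop2("labels must be 0/1")
  tp <- ids[labels == 1 & probs >= threshold]
  tn <- ids[labels == 0 & probs < threshold]
  if (length(tp) == 0) warning("no true positives")
  if (length(tn) == 0) warning("no true negatives")
  list(tp = tp, tn = tn)
}

#' Compare pathway enrichment between two sample groups
#'
#' Per-pathway two-sided Mann-Whitney U tests between the groups (typically
#' true-positive responders vs true-negative non-responders), with
#' Benjamini-Hochberg adjustment and a significance call at `alpha`.
#'
#' @param scores a `pathway_scores` object or samples x pathways matrix.
#' @param group_a,group_b disjoint vectors of sample ids (>= 3 each).
#' @param alpha FDR significance level.
#' @return data.frame(pathway, U, p, q, significant).
#' @export
compare_groups <- function(scores, group_a, group_b, alpha = 0.05) {
  m <- if (inherits(scores, "pathway_scores")) scores$scores else as.matrix(scores)
  if (length(intersect(group_a, group_b)) > 0) stop2("groups overlap")
  if (length(group_a) < 3 || length(group_b) < 3)
    stop2("both groups need >= 3 samples")
  missing <- setdiff(c(group_a, group_b), rownames(m))
  if (length(missing) > 0)
    stop2("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
  a <- m[group_a, , drop = FALSE]
  b <- m[group_b, , drop = FALSE]
  res <- lapply(seq_len(ncol(m)), function(j) {
    w <- suppressWarnings(stats::wilcox.test(a[, j], b[, j],
                                             alternative = "two.sided"))
    c(U = unname(w$statistic), p = w$p.value)
  })
  res <- do.call(rbind, res)
  q <- stats::p.adjust(res[, "p"], method = "BH")
  data.frame(pathway = colnames(m), U = res[, "U"], p = res[, "p"], q = q,
             significant = q < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}
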