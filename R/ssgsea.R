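# Single-sample gene-set enrichment: per-sample rank-based pathway activity
# scores (the EXP feature block), with an optional permutation significance
# matrix. The integrated (sum-of-running-sum) statistic is used by default;
# the classic max-deviation GSEA statistic is available for comparison.

#' Single-sample enrichment score for one gene set
#'
#' Genes are ranked by descending expression within the sample; the running
#' sum gains `|normalized rank|^weight_exponent` (normalized over in-set
#' genes) at in-set genes and loses `1/(N - m)` at out-of-set genes. The
#' integral score is the sum of the running sum over all positions; the max
#' score is the running sum's largest absolute deviation.
#'
#' @param sample_expression named numeric vector (one sample's expression).
#' @param gene_set character vector of member genes.
#' @param weight_exponent rank weighting exponent (0 = unweighted).
#' @param score `"integral"` (single-sample GSEA form, default) or `"max"`.
#' @param tie_seed seed for the fixed tie-breaking shuffle.
#' @return scalar enrichment score.
#' @export
ssgsea_score <- function(sample_expression, gene_set, weight_exponent = 0.25,
                         score = c("integral", "max"), tie_seed = 1) {
  score <- match.arg(score)
  genes <- names(sample_expression)
  if (is.null(genes)) stop2("sample_expression must be a named vector")
  set <- unique(gene_set)
  m <- sum(set %in% genes)
  if (m == 0) stop2("zero overlap between gene set and expression vector")
  if (m == length(genes)) stop2("gene set covers the entire universe (degenerate complement)")
  N <- length(genes)
  tb <- with_seed(tie_seed, sample(N))   # fixed tie-break order
  ord <- order(-sample_expression, tb)
  inset <- genes[ord] %in% set
  r <- (N - seq_len(N) + 1) / N          # normalized rank, descending
  w <- r^weight_exponent
  inc <- numeric(N)
  inc[inset] <- w[inset] / sum(w[inset])
  inc[!inset] <- -1 / (N - m)
  if (score == "integral") {
    # sum(cumsum(inc)) without materializing the running sum
    sum(inc * (N - seq_len(N) + 1))
  } else {
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
  }
}

#' Pathway-activity score matrix (EXP features)
#'
#' @param matrix an `expr_matrix` (typically harmonized).
#' @param collection a `gene_sets` collection.
#' @param weight_exponent rank weighting exponent.
#' @param normalize if TRUE, divide all scores by the range (max - min)
#'   across the whole matrix.
#' @param min_overlap pathways overlapping the gene universe by fewer genes
#'   are dropped with a warning.
#' @param score `"integral"` or `"max"`.
#' @param tie_seed tie-break seed.
#' @return a `pathway_scores` object: `scores` (samples x pathways),
#'   `pathway_names`, `sample_ids`, `pvalues` (NULL until
#'   [permutation_significance()] is run).
#' @export
ssgsea_matrix <- function(matrix, collection, weight_exponent = 0.25,
                          normalize = FALSE, min_overlap = 5,
                          score = c("integral", "max"), tie_seed = 1) {
  score <- match.arg(score)
  if (length(collection) == 0) stop2("empty gene-set collection")
  genes <- rownames(matrix$values)
  N <- length(genes)
  overlap <- vapply(collection, function(s) sum(unique(s) %in% genes), integer(1))
  keep <- overlap >= min_overlap & overlap < N
  if (!any(keep)) stop2("all pathways dropped (overlap < ", min_overlap, ")")
  if (any(!keep))
    warning("dropped ", sum(!keep), " pathway(s) below min_overlap: ",
            paste(utils::head(names(collection)[!keep], 5), collapse = ", "))
  sets <- collection[keep]

  tb <- with_seed(tie_seed, sample(N))
  coeff <- (N:1)                                  # weight of position i in the integral
  r_alpha <- ((N:1) / N)^weight_exponent
  csum_tot <- N * (N + 1) / 2
  n_samp <- ncol(matrix$values)
  out <- base::matrix(0, n_samp, length(sets),
                      dimnames = list(colnames(matrix$values), names(sets)))
  # position of every gene in each sample's descending ranking
  pos <- apply(matrix$values, 2, function(v) order(order(-v, tb)))
  rownames(pos) <- genes
  set_idx <- lapply(sets, function(s) which(genes %in% unique(s)))
  for (j in seq_len(n_samp)) {
    pj <- pos[, j]
    for (k in seq_along(sets)) {
      sp <- pj[set_idx[[k]]]
      m <- length(sp)
      if (score == "integral") {
        w <- r_alpha[sp]
        out[j, k] <- sum(coeff[sp] * w) / sum(w) -
          (csum_tot - sum(coeff[sp])) / (N - m)
      } else {
        inset <- logical(N); inset[sp] <- TRUE
        inc <- numeric(N)
        inc[inset] <- r_alpha[inset] / sum(r_alpha[inset])
        inc[!inset] <- -1 / (N - m)
        rs <- cumsum(inc)
        out[j, k] <- rs[which.max(abs(rs))]
      }
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  structure(list(scores = out, pathway_names = colnames(out),
                 sample_ids = rownames(out), pvalues = NULL,
                 params = list(weight_exponent = weight_exponent,
                               normalize = normalize, score = score,
                               min_overlap = min_overlap, tie_seed = tie_seed)),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("pathway_scores: %d samples x %d pathways%s\n",
              nrow(x$scores), ncol(x$scores),
              if (is.null(x$pvalues)) "" else " (+ permutation p-values)"))
  invisible(x)
}

#' Permutation significance of pathway scores
#'
#' For each pathway, `n_perm` random gene sets of the same size are scored on
#' every sample; p = (1 + #\{permuted score >= observed\}) / (1 + n_perm).
#'
#' @param matrix the `expr_matrix` the scores came from.
#' @param collection the same `gene_sets` collection.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param ... passed to [ssgsea_matrix()].
#' @return the `pathway_scores` object with `pvalues` filled in.
#' @export
permutation_significance <- function(matrix, collection, n_perm = 1000,
                                     seed = 1, ...) {
  if (n_perm < 100) stop2("n_perm must be >= 100")
  obs <- ssgsea_matrix(matrix, collection, ...)
  genes <- rownames(matrix$values)
  sizes <- vapply(collection[obs$pathway_names],
                  function(s) sum(unique(s) %in% genes), integer(1))
  count_ge <- base::matrix(0, nrow(obs$scores), ncol(obs$scores))
  perm_args <- list(...)
  perm_args$min_overlap <- 1
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm_sets <- lapply(sizes, function(m) sample(genes, m))
      names(perm_sets) <- names(sizes)
      ps <- do.call(ssgsea_matrix,
                    c(list(matrix, gene_sets(perm_sets, "PERM")), perm_args))
      count_ge <- count_ge + (ps$scores >= obs$scores)
    }
  })
  obs$pvalues <- (1 + count_ge) / (1 + n_perm)
  dimnames(obs$pvalues) <- dimnames(obs$scores)
  obs
}
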