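# Cross-dataset expression harmonization in three steps: restrict to the
# common gene set, standardize gene-wise on the pooled matrix, then estimate
# and remove per-batch location/scale effects with parametric empirical-Bayes
# shrinkage (Johnson-style ComBat model, batch-only, no covariates).

#' Restrict matrices to their common genes
#'
#' @param matrices list of `expr_matrix` objects (>= 2).
#' @return list of `expr_matrix`, all over the sorted gene intersection in
#'   identical order.
#' @export
intersect_genes <- function(matrices) {
  if (length(matrices) < 2) stop2("need at least two matrices")
  common <- rownames(matrices[[1]]$values)
  for (m in matrices[-1]) common <- intersect(common, rownames(m$values))
  if (length(common) == 0) stop2("empty gene intersection")
  common <- sort(common)
  lapply(matrices, function(m)
    expression_matrix(m$values[common, , drop = FALSE],
                      batch = m$batch, cancer_type = m$cancer_type))
}

#' Standardize each gene to mean 0, SD 1
#'
#' Uses the sample standard deviation (n - 1 denominator) over all pooled
#' samples. Zero-variance genes are dropped with a warning.
#'
#' @param matrix an `expr_matrix` with >= 2 samples.
#' @return list with `matrix` (standardized `expr_matrix`), `center`,
#'   `scale` (per retained gene), and `dropped` (zero-variance gene ids).
#' @export
standardize_genewise <- function(matrix) {
  v <- matrix$values
  if (ncol(v) < 2) stop2("need >= 2 samples to standardize")
  ctr <- rowMeans(v)
  sds <- apply(v, 1, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (all(drop)) stop2("all genes have zero variance")
  if (any(drop))
    warning(sum(drop), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(v)[drop], 5), collapse = ", "))
  v <- v[!drop, , drop = FALSE]
  z <- (v - ctr[!drop]) / sds[!drop]
  list(matrix = expression_matrix(z, batch = matrix$batch,
                                  cancer_type = matrix$cancer_type),
       center = ctr[!drop], scale = sds[!drop],
       dropped = rownames(matrix$values)[drop])
}

#' Fit the empirical-Bayes batch model
#'
#' On gene-wise standardized data, per-batch additive effects get a normal
#' prior and multiplicative effects an inverse-gamma prior, both with
#' method-of-moments hyperparameters; the conditional posterior estimates
#' gamma* and delta* are iterated to convergence.
#'
#' @param matrix standardized `expr_matrix` with >= 2 batches, each with
#'   >= 2 samples.
#' @param tol convergence tolerance on the iterative estimates.
#' @param max_iter iteration cap.
#' @return a `batch_model`: per-batch-per-gene `gamma_star` (additive) and
#'   `delta_star` (multiplicative, > 0), the raw estimates, hyperparameters,
#'   batch sizes and gene ids.
#' @export
fit_combat <- function(matrix, tol = 1e-4, max_iter = 100) {
  z <- matrix$values
  batches <- unique(matrix$batch)
  if (length(batches) < 2) stop2("need >= 2 batches")
  nb <- table(factor(matrix$batch, levels = batches))
  if (any(nb < 2))
    stop2("batch with a single sample: ", paste(batches[nb < 2], collapse = ", "))
  G <- nrow(z)
  gamma_hat <- delta_hat <- matrix(0, G, length(batches),
                                   dimnames = list(rownames(z), batches))
  for (b in batches) {
    j <- matrix$batch == b
    gamma_hat[, b] <- rowMeans(z[, j, drop = FALSE])
    delta_hat[, b] <- apply(z[, j, drop = FALSE], 1, stats::var)
  }
  # method-of-moments hyperpriors
  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2, stats::var)
  V <- colMeans(delta_hat)
  S2 <- apply(delta_hat, 2, stats::var)
  lambda <- (2 * S2 + V^2) / S2          # inverse-gamma shape
  theta <- (V * S2 + V^3) / S2           # inverse-gamma scale

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_along(batches)) {
    j <- matrix$batch == batches[b]
    n <- sum(j)
    zb <- z[, j, drop = FALSE]
    g_old <- gamma_hat[, b]; d_old <- delta_hat[, b]
    for (it in seq_len(max_iter)) {
      g_new <- (n * tau2[b] * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (n * tau2[b] + d_old)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (theta[b] + 0.5 * ss) / (n / 2 + lambda[b] - 1)
      delta <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new; d_old <- d_new
      if (delta < tol) break
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- d_old
  }
  structure(list(batches = batches, n_per_batch = as.integer(nb),
                 gamma_hat = gamma_hat, delta_hat = delta_hat,
                 gamma_star = gamma_star, delta_star = delta_star,
                 hyper = list(gamma_bar = gamma_bar, tau2 = tau2,
                              lambda = lambda, theta = theta),
                 gene_ids = rownames(z)),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d genes, %d batches (%s)\n",
              length(x$gene_ids), length(x$batches),
              paste(x$batches, collapse = ", ")))
  invisible(x)
}

#' Remove estimated batch effects
#'
#' Adjusted value = (z - gamma*_bg) / sqrt(delta*_bg). The input is already
#' gene-wise standardized to pooled mean 0, so re-centering on the grand mean
#' is a no-op and the output stays on the standardized scale.
#'
#' @param matrix standardized `expr_matrix`; its batches must all appear in
#'   the model.
#' @param model a `batch_model` from [fit_combat()].
#' @return adjusted `expr_matrix`.
#' @export
apply_combat <- function(matrix, model) {
  unknown <- setdiff(unique(matrix$batch), model$batches)
  if (length(unknown) > 0)
    stop2("unknown batch label: ", paste(unknown, collapse = ", "))
  if (!identical(rownames(matrix$values), model$gene_ids))
    stop2("gene set/order does not match the fitted model")
  z <- matrix$values
  out <- z
  for (b in model$batches) {
    j <- matrix$batch == b
    if (!any(j)) next
    out[, j] <- (z[, j, drop = FALSE] - model$gamma_star[, b]) /
      sqrt(model$delta_star[, b])
  }
  expression_matrix(out, batch = matrix$batch, cancer_type = matrix$cancer_type)
}

#' Run the full 3-step harmonization
#'
#' Gene intersection, pooled gene-wise standardization, empirical-Bayes batch
#' adjustment, in that order, on any number of input matrices (each sample
#' keeps its own batch label; typically one batch per source dataset).
#'
#' @param matrices list of `expr_matrix` objects (a single pre-merged matrix
#'   with multiple batches is also accepted).
#' @return one joint adjusted `expr_matrix` with batch labels preserved; the
#'   fitted `batch_model` and standardization parameters are attached as
#'   attributes `batch_model` and `standardization`.
#' @export
harmonize_run <- function(matrices) {
  if (inherits(matrices, "expr_matrix")) matrices <- list(matrices)
  if (length(matrices) > 1) matrices <- intersect_genes(matrices)
  joint <- expression_matrix(
    do.call(cbind, lapply(matrices, function(m) m$values)),
    batch = unlist(lapply(matrices, function(m) m$batch)),
    cancer_type = unlist(lapply(matrices, function(m) m$cancer_type)))
  std <- standardize_genewise(joint)
  model <- fit_combat(std$matrix)
  adj <- apply_combat(std$matrix, model)
  attr(adj, "batch_model") <- model
  attr(adj, "standardization") <- list(center = std$center, scale = std$scale,
                                       dropped = std$dropped)
  adj
}
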