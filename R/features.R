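# Assembly of the model input: one row per (sample, drug) response pair,
# concatenating the sample's pathway activities (EXP), the drug's fingerprint
# (CHEM) and its network-propagated target enrichment (DGNet).

#' Build the concatenated feature table
#'
#' @param exp_scores a `pathway_scores` object (samples x pathways).
#' @param chem CHEM matrix from [chem_matrix()] (drugs x bits).
#' @param dgnet DGNet matrix from [dgnet_matrix()] (drugs x pathways).
#' @param response a `response_table`; every row must reference a scored
#'   sample and a featurized drug.
#' @param cancer_type optional named vector (by sample id) carried through
#'   for per-cancer breakdowns.
#' @return a `feature_table`: `x` (matrix), `y`, `sample_id`, `drug_id`,
#'   `kind`, `blocks` (column index per block), `cancer_type`, `extra`
#'   (additional response columns such as `neg_log10_ic50`).
#' @export
build_feature_table <- function(exp_scores, chem, dgnet, response,
                                cancer_type = NULL) {
  miss_s <- setdiff(response$sample_id, rownames(exp_scores$scores))
  if (length(miss_s) > 0)
    stop2("response references unscored samples: ",
          paste(utils::head(miss_s, 5), collapse = ", "))
  miss_d <- setdiff(response$drug_id, rownames(chem))
  if (length(miss_d) > 0)
    stop2("response references unknown drugs: ",
          paste(utils::head(miss_d, 5), collapse = ", "))
  if (!identical(rownames(chem), rownames(dgnet)))
    stop2("chem and dgnet matrices must cover the same drugs in the same order")
  exp_block <- exp_scores$scores[response$sample_id, , drop = FALSE]
  colnames(exp_block) <- paste0("EXP_", exp_scores$pathway_names)
  x <- cbind(exp_block,
             chem[response$drug_id, , drop = FALSE],
             dgnet[response$drug_id, , drop = FALSE])
  rownames(x) <- NULL
  n_exp <- ncol(exp_block); n_chem <- ncol(chem); n_dg <- ncol(dgnet)
  extra_cols <- setdiff(names(response), c("sample_id", "drug_id", "response"))
  structure(list(
    x = x, y = response$response,
    sample_id = response$sample_id, drug_id = response$drug_id,
    kind = attr(response, "kind"),
    cancer_type = if (is.null(cancer_type)) NULL
    else unname(cancer_type[response$sample_id]),
    blocks = list(EXP = seq_len(n_exp),
                  CHEM = n_exp + seq_len(n_chem),
                  DGNET = n_exp + n_chem + seq_len(n_dg)),
    extra = if (length(extra_cols)) as.list(response[extra_cols]) else list()),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d rows (%d samples x %d drugs), %d features (EXP %d | CHEM %d | DGNET %d), %s outcome\n",
              nrow(x$x), length(unique(x$sample_id)), length(unique(x$drug_id)),
              ncol(x$x), length(x$blocks$EXP), length(x$blocks$CHEM),
              length(x$blocks$DGNET), x$kind))
  invisible(x)
}

#' Subset a feature table by row index
#' @param features `feature_table`.
#' @param rows integer or logical index.
#' @return subsetted `feature_table`.
#' @export
subset_features <- function(features, rows) {
  out <- features
  out$x <- features$x[rows, , drop = FALSE]
  out$y <- features$y[rows]
  out$sample_id <- features$sample_id[rows]
  out$drug_id <- features$drug_id[rows]
  if (!is.null(features$cancer_type)) out$cancer_type <- features$cancer_type[rows]
  out$extra <- lapply(features$extra, function(v) v[rows])
  out
}
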