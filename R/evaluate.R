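# Repeated cross-validation and metrics: AUROC (rank/Mann-Whitney form),
# RMSE, per-drug / per-cancer / source-panel-membership breakdowns, and the
# Mann-Whitney comparison of two models' fold-score distributions.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outranks
#' a random negative, ties counted one half.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric prediction scores.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) stop2("length mismatch")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop2("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Root mean squared error
#' @param y_true,y_pred equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop2("empty input")
  if (length(y_true) != length(y_pred)) stop2("length mismatch")
  sqrt(mean((y_true - y_pred)^2))
}

#' Compare two models' fold scores (Mann-Whitney U)
#'
#' Exact two-sided p for samples of up to 8 per side without ties, normal
#' approximation with tie correction otherwise.
#'
#' @param fold_scores_a,fold_scores_b numeric vectors (>= 3 each).
#' @param alternative passed to [stats::wilcox.test()].
#' @return p-value.
#' @export
compare_models <- function(fold_scores_a, fold_scores_b,
                           alternative = "two.sided") {
  if (length(fold_scores_a) < 3 || length(fold_scores_b) < 3)
    stop2("need >= 3 fold scores per model")
  ties <- anyDuplicated(c(fold_scores_a, fold_scores_b)) > 0
  small <- length(fold_scores_a) <= 8 && length(fold_scores_b) <= 8
  suppressWarnings(
    stats::wilcox.test(fold_scores_a, fold_scores_b, alternative = alternative,
                       exact = small && !ties)$p.value)
}

#' Repeated stratified cross-validation
#'
#' `k`-fold cross-validation repeated `repeats` times. Classification folds
#' are stratified by (drug, label); regression folds are random. The fitted
#' model is discarded between folds; pooled out-of-fold predictions are kept
#' for per-group breakdowns.
#'
#' @param features a `feature_table`.
#' @param fit function(train_features) -> model.
#' @param predict_fun function(model, x_matrix) -> numeric predictions
#'   (defaults to [predict()]).
#' @param metric `"auroc"` or `"rmse"`.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed RNG seed; fold assignments are deterministic under it.
#' @return a `cv_result`: `fold_scores` (length k*repeats), `mean`, `sd`,
#'   `predictions` (pooled out-of-fold rows) and `metric`.
#' @export
repeated_cv <- function(features, fit, predict_fun = NULL,
                        metric = c("auroc", "rmse"), k = 5, repeats = 5,
                        seed = 1) {
  metric <- match.arg(metric)
  if (is.null(predict_fun)) predict_fun <- function(m, x) predict(m, x)
  n <- nrow(features$x)
  if (n < k) stop2("fewer rows than folds")
  strata <- if (metric == "auroc") paste(features$drug_id, features$y)
  else rep("all", n)
  fold_scores <- numeric(0)
  preds <- list()
  for (r in seq_len(repeats)) {
    folds <- draw_folds(n, k, strata, metric, features$y,
                        seed = child_seed(seed, paste0("rep", r)))
    for (f in seq_len(k)) {
      tr <- subset_features(features, folds != f)
      te <- subset_features(features, folds == f)
      model <- fit(tr)
      p <- predict_fun(model, te$x)
      score <- if (metric == "auroc") auroc(te$y, p) else rmse(te$y, p)
      fold_scores <- c(fold_scores, score)
      preds[[length(preds) + 1]] <- data.frame(
        sample_id = te$sample_id, drug_id = te$drug_id,
        cancer_type = te$cancer_type %||% NA_character_,
        y = te$y, pred = p, rep = r, fold = f, stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, preds)
  structure(list(fold_scores = fold_scores, mean = mean(fold_scores),
                 sd = stats::sd(fold_scores), metric = metric, k = k,
                 repeats = repeats, predictions = predictions),
            class = "cv_result")
}

# stratified fold assignment; re-draws (max 10) if a fold loses a class
draw_folds <- function(n, k, strata, metric, y, seed) {
  with_seed(seed, {
    for (attempt in seq_len(10)) {
      folds <- integer(n)
      for (s in unique(strata)) {
        rows <- which(strata == s)
        folds[rows] <- sample(rep_len(sample(k), length(rows)))
      }
      if (metric != "auroc") return(folds)
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[folds == f])) == 2, logical(1)))
      if (ok) return(folds)
      warning("fold lost a class; re-drawing (attempt ", attempt, ")")
    }
    stop2("could not draw class-complete folds in 10 attempts")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s over %d x %d folds = %.3f ± %.3f\n",
              toupper(x$metric), x$k, x$repeats, x$mean, x$sd))
  invisible(x)
}

#' Format a cv_result as "mean +/- SD"
#' @param x `cv_result`.
#' @param digits significant digits.
#' @return character scalar.
#' @export
format_mean_sd <- function(x, digits = 2) {
  sprintf("%.*f ± %.*f", digits, x$mean, digits, x$sd)
}

#' Per-group performance breakdown
#'
#' Metric per drug or per cancer type on pooled out-of-fold predictions;
#' groups with fewer than `min_group_n` rows (or, for AUROC, a single class)
#' are excluded. Means are reported separately for groups present in the
#' source panel and groups that are not.
#'
#' @param predictions the `predictions` data.frame of a [repeated_cv()]
#'   result (pooled over folds; repeated rows across repeats are averaged
#'   per (sample, drug) first).
#' @param group_by `"drug_id"` or `"cancer_type"`.
#' @param membership named logical vector: is the group present in the
#'   source (cell-line) panel?
#' @param min_group_n minimum rows per retained group.
#' @param metric `"auroc"` or `"rmse"`.
#' @return list with `table` (group, n, metric, member), `member_mean`,
#'   `nonmember_mean`.
#' @export
per_group_performance <- function(predictions, group_by = c("drug_id", "cancer_type"),
                                  membership = NULL, min_group_n = 5,
                                  metric = c("auroc", "rmse")) {
  group_by <- match.arg(group_by)
  metric <- match.arg(metric)
  # average repeated out-of-fold predictions per (sample, drug)
  key <- paste(predictions$sample_id, predictions$drug_id)
  agg <- stats::aggregate(predictions$pred, by = list(key = key), FUN = mean)
  first <- predictions[!duplicated(key), ]
  first$pred <- agg$x[match(paste(first$sample_id, first$drug_id), agg$key)]
  rows <- split(seq_len(nrow(first)), first[[group_by]])
  out <- list()
  for (g in names(rows)) {
    idx <- rows[[g]]
    if (length(idx) < min_group_n) next
    val <- if (metric == "auroc") {
      if (length(unique(first$y[idx])) < 2) {
        warning("group ", g, " has a single class; excluded")
        next
      }
      auroc(first$y[idx], first$pred[idx])
    } else rmse(first$y[idx], first$pred[idx])
    out[[g]] <- data.frame(group = g, n = length(idx), value = val,
                           member = isTRUE(membership[g]),
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    warning("no group meets min_group_n = ", min_group_n)
    return(list(table = data.frame(group = character(0), n = integer(0),
                                   value = numeric(0), member = logical(0)),
                member_mean = NA_real_, nonmember_mean = NA_real_))
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  list(table = tab,
       member_mean = if (any(tab$member)) mean(tab$value[tab$member]) else NA_real_,
       nonmember_mean = if (any(!tab$member)) mean(tab$value[!tab$member]) else NA_real_)
}
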