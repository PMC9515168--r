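# Transfer of the pre-trained cell-line network to a target task: copy the
# first k hidden layers (frozen or retrainable), optionally add new hidden
# layers, attach a task head, fine-tune under BCE (classification) or MSE
# (regression), with per-drug imbalance subsampling and a Gaussian-process
# Bayesian hyperparameter search.

#' Transfer configuration
#'
#' @param n_transfer_layers how many leading hidden layers to copy from the
#'   pre-trained model (0..depth).
#' @param retrain_transferred if FALSE, copied layers are frozen.
#' @param new_hidden_layers widths of additional hidden layers appended
#'   after the transferred ones.
#' @param head `"classification"` or `"regression"`.
#' @param train a [train_config()] for fine-tuning (BCE or MSE loss). The
#'   default uses a 20% validation split: target cohorts are small, and
#'   early stopping on a larger split is much more stable there.
#' @param head_warmup_epochs epochs of head-only training (transferred
#'   layers held fixed) before the main fine-tuning phase; 0 disables. A
#'   freshly initialized head otherwise scrambles the transferred
#'   representation before it can align with it.
#' @param head_warmup_lr learning rate during the warmup phase.
#' @param subsample_ratio non-responders kept per responder (default 3,
#'   i.e. 1:3).
#' @param seed seed for new-layer initialization.
#' @return `transfer_config` list.
#' @export
transfer_config <- function(n_transfer_layers = 4, retrain_transferred = TRUE,
                            new_hidden_layers = integer(0),
                            head = c("classification", "regression"),
                            train = NULL, head_warmup_epochs = 30,
                            head_warmup_lr = 2e-3, subsample_ratio = 3,
                            seed = 1) {
  head <- match.arg(head)
  if (is.null(train))
    train <- train_config(loss = if (head == "classification") "bce" else "mse",
                          val_fraction = 0.2, seed = seed)
  if (subsample_ratio < 1) stop2("subsample_ratio must be >= 1")
  structure(list(n_transfer_layers = n_transfer_layers,
                 retrain_transferred = retrain_transferred,
                 new_hidden_layers = new_hidden_layers, head = head,
                 train = train, head_warmup_epochs = head_warmup_epochs,
                 head_warmup_lr = head_warmup_lr,
                 subsample_ratio = subsample_ratio, seed = seed),
            class = "transfer_config")
}

#' Build a target-task network from a pre-trained model
#'
#' The first `n_transfer_layers` hidden layers are initialized from the
#' pre-trained weights (frozen unless `retrain_transferred`); any
#' `new_hidden_layers` and the task head are freshly initialized.
#'
#' @param pretrained a trained `sensitivity_model`.
#' @param cfg a [transfer_config()].
#' @return an untrained-on-target `sensitivity_model`.
#' @export
transfer_build <- function(pretrained, cfg = transfer_config()) {
  k <- cfg$n_transfer_layers
  depth <- length(pretrained$widths)
  if (k < 0 || k > depth)
    stop2("n_transfer_layers must be in 0..", depth)
  widths <- c(pretrained$widths[seq_len(k)], cfg$new_hidden_layers)
  if (length(widths) == 0)
    stop2("network needs at least one hidden layer; transfer some or add new ones")
  model <- build_network(pretrained$input_dim, head = cfg$head, widths = widths,
                         dropout = cfg$train$dropout, seed = cfg$seed)
  if (k > 0) {
    for (l in seq_len(k)) model$layers[[l]] <- pretrained$layers[[l]]
    model$provenance$pretrained[seq_len(k)] <- TRUE
    model$provenance$frozen[seq_len(k)] <- !cfg$retrain_transferred
  }
  model
}

#' Subsample non-responders to a fixed per-drug ratio
#'
#' All responders are kept; non-responders are sampled without replacement
#' down to `ratio` per responder (or all of them, if fewer). Drugs with zero
#' responders are dropped with a warning.
#'
#' @param table dichotomous `response_table`.
#' @param ratio non-responders per responder (default 3).
#' @param seed RNG seed.
#' @return subsampled `response_table` (original row order preserved).
#' @export
subsample_nonresponders <- function(table, ratio = 3, seed = 1) {
  if (attr(table, "kind") != "dichotomous") stop2("need a dichotomous table")
  if (ratio < 1) stop2("ratio must be >= 1")
  with_seed(seed, {
    keep <- logical(nrow(table))
    for (d in unique(table$drug_id)) {
      rows <- which(table$drug_id == d)
      resp <- rows[table$response[rows] == 1]
      nonr <- rows[table$response[rows] == 0]
      if (length(resp) == 0) {
        warning("drug ", d, " has no responders; dropped")
        next
      }
      keep[resp] <- TRUE
      n_keep <- min(length(nonr), ratio * length(resp))
      if (n_keep > 0) keep[sample(nonr, n_keep)] <- TRUE
    }
    out <- table[keep, , drop = FALSE]
    attr(out, "kind") <- "dichotomous"
    class(out) <- class(table)
    rownames(out) <- NULL
    out
  })
}

#' Fine-tune a (transferred) network on the target task
#'
#' Same early-stopping/clipping contract as pre-training; frozen layers are
#' never updated (bitwise). When the model carries retrainable transferred
#' layers and `head_warmup_epochs > 0`, the new layers are first trained
#' alone (transferred layers temporarily held fixed) before the joint
#' phase. The training log records which layers updated.
#'
#' @param model model from [transfer_build()] (or [build_network()]).
#' @param features target `feature_table`.
#' @param cfg a [transfer_config()] (its `train` block drives the fit) or a
#'   bare [train_config()].
#' @return fine-tuned `sensitivity_model`.
#' @export
fine_tune <- function(model, features, cfg = transfer_config()) {
  config <- if (inherits(cfg, "train_config")) cfg else cfg$train
  if (config$loss == "bce" && features$kind != "dichotomous")
    stop2("bce fine-tuning needs a dichotomous outcome")
  if (config$loss %in% c("mse", "rmse") && features$kind != "continuous")
    stop2("regression fine-tuning needs a continuous outcome")
  warmup <- if (inherits(cfg, "transfer_config")) cfg$head_warmup_epochs else 0
  retrainable <- model$provenance$pretrained & !model$provenance$frozen
  if (warmup > 0 && any(retrainable) && !all(model$provenance$pretrained)) {
    wcfg <- config
    wcfg$max_epochs <- warmup
    wcfg$learning_rate <- cfg$head_warmup_lr
    wcfg$seed <- child_seed(config$seed, "head_warmup")
    frozen_before <- model$provenance$frozen
    model$provenance$frozen[retrainable] <- TRUE
    model <- fit_network(model, features$x, features$y, wcfg,
                         groups = features$drug_id)
    model$provenance$frozen <- frozen_before
  }
  out <- fit_network(model, features$x, features$y, config,
                     groups = features$drug_id)
  out$updated_layers <- which(!out$provenance$frozen)
  out
}

# ---- Gaussian-process Bayesian hyperparameter search -----------------------

#' Default transfer search space
#'
#' Dimensions mirror the tunable fine-tuning choices: transferred depth,
#' retrain flag, new-layer count and width, dropout, learning rate and batch
#' size. Each dimension is a list with `name`, `type` ("choice", "uniform",
#' "loguniform" or "int") and `values` (choices) or `bounds`.
#'
#' @param depth pre-trained depth (caps `n_transfer_layers`).
#' @return list of dimension specs.
#' @export
default_search_space <- function(depth = 4) {
  list(
    list(name = "n_transfer_layers", type = "choice", values = 0:depth),
    list(name = "retrain_transferred", type = "choice", values = c(TRUE, FALSE)),
    list(name = "n_new_layers", type = "choice", values = 0:2),
    list(name = "new_layer_width", type = "choice", values = c(8, 16, 32, 64)),
    list(name = "dropout", type = "uniform", bounds = c(0, 0.3)),
    list(name = "learning_rate", type = "loguniform", bounds = c(1e-4, 1e-2)),
    list(name = "batch_size", type = "choice", values = c(16, 32, 64, 128))
  )
}

sample_point <- function(space) {
  pt <- list()
  for (d in space) {
    pt[[d$name]] <- switch(d$type,
      choice = d$values[[sample(length(d$values), 1)]],
      uniform = stats::runif(1, d$bounds[1], d$bounds[2]),
      loguniform = exp(stats::runif(1, log(d$bounds[1]), log(d$bounds[2]))),
      int = sample(seq(d$bounds[1], d$bounds[2]), 1))
  }
  pt
}

encode_point <- function(space, pt) {
  vapply(space, function(d) {
    v <- pt[[d$name]]
    switch(d$type,
      choice = (match(list(v), as.list(d$values)) - 1) / max(1, length(d$values) - 1),
      uniform = (v - d$bounds[1]) / diff(d$bounds),
      loguniform = (log(v) - log(d$bounds[1])) / diff(log(d$bounds)),
      int = (v - d$bounds[1]) / max(1, diff(d$bounds)))
  }, numeric(1))
}

# GP posterior with RBF kernel on [0,1]^d-encoded points
gp_fit_predict <- function(X, y, Xnew, lengthscale = 0.3, nugget = 1e-6) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * lengthscale^2))
  }
  mu <- mean(y); sdy <- stats::sd(y); if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  K <- k(X, X) + diag(nugget, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  Ks <- k(Xnew, X)
  pred <- as.numeric(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  var <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = pred * sdy + mu, sd = sqrt(var) * sdy)
}

expected_improvement <- function(mu, sd, best) {
  z <- (mu - best) / sd
  (mu - best) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Sequential model-based hyperparameter search
#'
#' Gaussian-process surrogate (RBF kernel on the unit-cube-encoded space)
#' with expected improvement, maximizing the objective. The default
#' objective is the mean metric over an inner 3-fold split of the training
#' data (AUROC for classification, negative RMSE for regression).
#'
#' @param pretrained pre-trained `sensitivity_model`.
#' @param features target `feature_table`.
#' @param search_space list of dimension specs ([default_search_space()]).
#' @param budget total number of evaluated configurations (>= 1).
#' @param seed RNG seed; the search is deterministic under it.
#' @param objective optional function(point) -> scalar to maximize,
#'   overriding the inner-CV evaluator (used for testing the optimizer).
#' @param n_init random initial design size.
#' @return list with `best` (point + objective value as a
#'   [transfer_config()]-ready list) and `trace` (every evaluated point).
#' @export
hyperparameter_search <- function(pretrained, features, search_space = NULL,
                                  budget = 20, seed = 1, objective = NULL,
                                  n_init = 5) {
  if (budget < 1) stop2("budget must be >= 1")
  if (is.null(search_space)) search_space <- default_search_space(
    depth = length(pretrained$widths))
  if (length(search_space) == 0) stop2("empty search space")
  if (is.null(objective))
    objective <- function(pt) inner_cv_objective(pretrained, features, pt,
                                                 seed = child_seed(seed, "inner"))
  with_seed(seed, {
    pts <- list(); ys <- numeric(0)
    n_init <- min(n_init, budget)
    for (i in seq_len(n_init)) {
      pt <- sample_point(search_space)
      pts[[i]] <- pt
      ys[i] <- objective(pt)
    }
    while (length(ys) < budget) {
      X <- t(vapply(pts, function(p) encode_point(search_space, p),
                    numeric(length(search_space))))
      cand <- lapply(seq_len(200), function(i) sample_point(search_space))
      Xc <- t(vapply(cand, function(p) encode_point(search_space, p),
                     numeric(length(search_space))))
      post <- gp_fit_predict(X, ys, Xc)
      ei <- expected_improvement(post$mean, post$sd, max(ys))
      pt <- cand[[which.max(ei)]]
      pts[[length(pts) + 1]] <- pt
      ys[length(ys) + 1] <- objective(pt)
    }
    best_i <- which.max(ys)
    trace <- do.call(rbind, lapply(seq_along(pts), function(i)
      data.frame(eval = i, objective = ys[i],
                 as.data.frame(pts[[i]], stringsAsFactors = FALSE))))
    list(best = c(pts[[best_i]], list(objective = ys[best_i])), trace = trace)
  })
}

# mean inner-3-fold validation metric for one search point
inner_cv_objective <- function(pretrained, features, pt, seed = 1, k = 3) {
  task <- if (features$kind == "dichotomous") "classification" else "regression"
  k_tl <- pt$n_transfer_layers %||% length(pretrained$widths)
  new_widths <- rep(pt$new_layer_width %||% 16, pt$n_new_layers %||% 0)
  # an all-scratch point with no new layers means: pretrained architecture,
  # freshly initialized
  if (k_tl == 0 && length(new_widths) == 0) new_widths <- pretrained$widths
  cfg <- transfer_config(
    n_transfer_layers = k_tl,
    retrain_transferred = pt$retrain_transferred %||% TRUE,
    new_hidden_layers = new_widths,
    head = task,
    train = train_config(
      loss = if (task == "classification") "bce" else "mse",
      learning_rate = pt$learning_rate %||% 4e-4,
      dropout = pt$dropout %||% 0.1,
      batch_size = pt$batch_size %||% 128,
      max_epochs = pt$max_epochs %||% 60, seed = seed),
    seed = seed)
  n <- nrow(features$x)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  scores <- vapply(seq_len(k), function(f) {
    tr <- subset_features(features, folds != f)
    te <- subset_features(features, folds == f)
    m <- transfer_build(pretrained, cfg)
    m <- fine_tune(m, tr, cfg)
    pred <- predict(m, te$x)
    if (task == "classification") {
      if (length(unique(te$y)) < 2) return(NA_real_)
      auroc(te$y, pred)
    } else -rmse(te$y, pred)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}
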