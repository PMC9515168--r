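# The sensitivity network: a feed-forward regression/classification model
# with ELU hidden layers, neuron-level dropout, Adamax updates, post-update
# weight clipping and patience-based early stopping, implemented in base R
# matrix operations so training is deterministic under a seed on any CPU.

MODEL_FORMAT_VERSION <- "pathdrp-model-1"

#' Training configuration
#'
#' Defaults follow the pre-training recipe: RMSE loss, Adamax with learning
#' rate 4e-4, 10% neuron dropout, weights clipped to [-5, 5] after every
#' update, early stopping with patience 30 on a held-out validation split.
#'
#' @param learning_rate Adamax step size.
#' @param patience epochs without validation improvement before stopping.
#' @param dropout neuron dropout probability in hidden layers.
#' @param clip_range length-2 ordered numeric; weights are clamped into it
#'   after every gradient update.
#' @param optimizer only `"adamax"` is implemented.
#' @param loss `"rmse"`, `"mse"` or `"bce"`.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param val_fraction fraction of the training data held out for early
#'   stopping (stratified by drug when drug ids are supplied).
#' @param seed RNG seed controlling initialization, splits, shuffling and
#'   dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 4e-4, patience = 30, dropout = 0.10,
                         clip_range = c(-5, 5), optimizer = "adamax",
                         loss = c("rmse", "mse", "bce"), batch_size = 128,
                         max_epochs = 300, val_fraction = 0.1, seed = 1) {
  loss <- match.arg(loss)
  if (patience < 1) stop2("patience must be >= 1")
  if (clip_range[1] >= clip_range[2]) stop2("clip bounds must be ordered")
  if (optimizer != "adamax") stop2("only the adamax optimizer is implemented")
  structure(list(learning_rate = learning_rate, patience = patience,
                 dropout = dropout, clip_range = clip_range,
                 optimizer = optimizer, loss = loss, batch_size = batch_size,
                 max_epochs = max_epochs, val_fraction = val_fraction,
                 seed = seed),
            class = "train_config")
}

elu <- function(x) ifelse(x > 0, x, expm1(x))
elu_grad <- function(pre) ifelse(pre > 0, 1, exp(pre))

init_layer <- function(n_in, n_out) {
  s <- 1 / sqrt(n_in)
  list(W = base::matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out),
       b = stats::runif(n_out, -s, s))
}

#' Build an untrained sensitivity network
#'
#' Hidden layers use ELU; the output layer is linear (regression head) or
#' sigmoid (classification head).
#'
#' @param input_dim number of input features.
#' @param head `"regression"` or `"classification"`.
#' @param widths hidden-layer widths.
#' @param dropout hidden-layer dropout probability used during training.
#' @param seed initialization seed.
#' @return a `sensitivity_model`.
#' @export
build_network <- function(input_dim, head = c("regression", "classification"),
                          widths = c(1000, 800, 500, 100), dropout = 0.10,
                          seed = 1) {
  head <- match.arg(head)
  if (input_dim < 1) stop2("input_dim must be >= 1")
  if (length(widths) < 1 || any(widths <= 0)) stop2("non-positive layer width")
  dims <- c(input_dim, widths, 1)
  layers <- with_seed(seed, lapply(seq_len(length(dims) - 1), function(i)
    init_layer(dims[i], dims[i + 1])))
  structure(list(input_dim = input_dim, widths = widths, head = head,
                 dropout = dropout, layers = layers,
                 provenance = data.frame(layer = seq_along(layers),
                                         pretrained = FALSE, frozen = FALSE),
                 log = NULL, version = MODEL_FORMAT_VERSION),
            class = "sensitivity_model")
}

#' Number of trainable parameters
#' @param model a `sensitivity_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

forward_pass <- function(model, X, dropout = 0) {
  L <- length(model$layers)
  act <- vector("list", L + 1)
  pre <- vector("list", L)
  mask <- vector("list", L)
  act[[1]] <- X
  for (l in seq_len(L)) {
    z <- act[[l]] %*% model$layers[[l]]$W
    z <- sweep(z, 2, model$layers[[l]]$b, "+")
    pre[[l]] <- z
    if (l < L) {
      a <- elu(z)
      if (dropout > 0) {
        m <- base::matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                          nrow(a), ncol(a))
        mask[[l]] <- m
        a <- a * m
      }
      act[[l + 1]] <- a
    } else {
      act[[l + 1]] <- if (model$head == "classification") stats::plogis(z) else z
    }
  }
  list(act = act, pre = pre, mask = mask, yhat = as.numeric(act[[L + 1]]))
}

loss_value <- function(loss, y, yhat) {
  switch(loss,
         rmse = sqrt(mean((yhat - y)^2)),
         mse = mean((yhat - y)^2),
         bce = {
           p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
           -mean(y * log(p) + (1 - y) * log(1 - p))
         })
}

# gradient of the loss wrt the output-layer pre-activation
output_delta <- function(model, loss, y, fw) {
  n <- length(y)
  yhat <- fw$yhat
  if (loss == "bce") {
    (yhat - y) / n                        # sigmoid + BCE combined
  } else {
    d <- if (loss == "mse") 2 * (yhat - y) / n
    else {
      r <- sqrt(mean((yhat - y)^2))
      if (r == 0) rep(0, n) else (yhat - y) / (n * r)
    }
    if (model$head == "classification") d <- d * yhat * (1 - yhat)
    d
  }
}

clip_layer <- function(l, range) {
  l$W[] <- pmin(pmax(l$W, range[1]), range[2])
  l$b <- pmin(pmax(l$b, range[1]), range[2])
  l
}

# One SGD step on a minibatch; returns updated model + optimizer state.
adamax_step <- function(model, state, X, y, config, t) {
  L <- length(model$layers)
  fw <- forward_pass(model, X, dropout = config$dropout)
  delta <- base::matrix(output_delta(model, config$loss, y, fw), ncol = 1)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr_t <- config$learning_rate / (1 - b1^t)
  for (l in rev(seq_len(L))) {
    frozen <- model$provenance$frozen[l]
    gW <- crossprod(fw$act[[l]], delta)
    gb <- colSums(delta)
    if (l > 1) {
      back <- delta %*% t(model$layers[[l]]$W)
      if (!is.null(fw$mask[[l - 1]])) back <- back * fw$mask[[l - 1]]
      delta <- back * elu_grad(fw$pre[[l - 1]])
    }
    if (frozen) next
    st <- state[[l]]
    st$mW <- b1 * st$mW + (1 - b1) * gW
    st$uW <- pmax(b2 * st$uW, abs(gW))
    st$mb <- b1 * st$mb + (1 - b1) * gb
    st$ub <- pmax(b2 * st$ub, abs(gb))
    model$layers[[l]]$W <- model$layers[[l]]$W - lr_t * st$mW / (st$uW + eps)
    model$layers[[l]]$b <- model$layers[[l]]$b - lr_t * st$mb / (st$ub + eps)
    model$layers[[l]] <- clip_layer(model$layers[[l]], config$clip_range)
    state[[l]] <- st
  }
  list(model = model, state = state)
}

# stratified validation indices (>= 1 per stratum where possible)
val_split <- function(n, fraction, strata = NULL) {
  if (fraction <= 0) return(integer(0))
  if (is.null(strata)) strata <- rep(1, n)
  idx <- integer(0)
  for (s in unique(strata)) {
    rows <- which(strata == s)
    k <- max(1, round(fraction * length(rows)))
    k <- min(k, length(rows) - 1)
    if (k > 0) idx <- c(idx, sample(rows, k))
  }
  sort(idx)
}

#' Fit a sensitivity network
#'
#' Core training loop shared by pre-training and fine-tuning: minibatch
#' Adamax with dropout, post-update clipping, and early stopping on a
#' held-out validation split with best-epoch weight restoration. Layers
#' flagged frozen are never updated.
#'
#' @param model `sensitivity_model` (weights are the starting point).
#' @param x numeric feature matrix (rows = instances).
#' @param y numeric response vector (0/1 for `"bce"`).
#' @param config a [train_config()].
#' @param groups optional per-row group labels (e.g. drug ids) used to
#'   stratify the validation split (crossed with the label for
#'   classification).
#' @return the trained model, with `log` holding per-epoch train/validation
#'   loss and `best_epoch`.
#' @export
fit_network <- function(model, x, y, config = train_config(), groups = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (ncol(x) != model$input_dim) stop2("feature dimension mismatch")
  if (nrow(x) < 2) stop2("need >= 2 rows to fit")
  if (config$loss == "bce" && model$head != "classification")
    stop2("bce loss requires a classification head")
  with_seed(config$seed, {
    strata <- if (is.null(groups)) NULL
    else if (model$head == "classification") paste(groups, y)
    else as.character(groups)
    vi <- val_split(nrow(x), config$val_fraction, strata)
    if (config$val_fraction > 0 && length(vi) == 0)
      stop2("empty validation split")
    ti <- setdiff(seq_len(nrow(x)), vi)
    if (length(ti) == 0) stop2("empty training split")
    xt <- x[ti, , drop = FALSE]; yt <- y[ti]
    xv <- x[vi, , drop = FALSE]; yv <- y[vi]
    has_val <- length(vi) > 0

    state <- lapply(model$layers, function(l)
      list(mW = l$W * 0, uW = l$W * 0, mb = l$b * 0, ub = l$b * 0))
    best <- model$layers
    best_val <- Inf; best_epoch <- 0; wait <- 0; t <- 0
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(yt))
      nb <- ceiling(length(yt) / config$batch_size)
      for (bi in seq_len(nb)) {
        rows <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, length(yt))]
        t <- t + 1
        stepped <- adamax_step(model, state, xt[rows, , drop = FALSE], yt[rows],
                               config, t)
        model <- stepped$model; state <- stepped$state
      }
      tr_loss <- loss_value(config$loss, yt, forward_pass(model, xt)$yhat)
      vl_loss <- if (has_val) loss_value(config$loss, yv, forward_pass(model, xv)$yhat)
      else NA_real_
      if (is.nan(tr_loss) || (has_val && is.nan(vl_loss)))
        stop2("NaN loss at epoch ", epoch)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = vl_loss))
      if (has_val) {
        if (vl_loss < best_val) {
          best_val <- vl_loss; best <- model$layers; best_epoch <- epoch; wait <- 0
        } else {
          wait <- wait + 1
          if (wait >= config$patience) break
        }
      } else {
        best <- model$layers; best_epoch <- epoch
      }
    }
    model$layers <- best
    model$log <- log
    model$best_epoch <- best_epoch
    model
  })
}

#' Pre-train the cell-line sensitivity model
#'
#' Fits the regression network on cell-line features against a continuous
#' sensitivity target: the 1-AUC-style outcome carried by the feature table
#' (default) or a potency-style `neg_log10_ic50` column when present.
#'
#' @param features a `feature_table` (see [build_feature_table()]).
#' @param config a [train_config()] (RMSE loss by default).
#' @param widths hidden-layer widths.
#' @param target which continuous target to regress on.
#' @return trained `sensitivity_model` with all layers flagged pretrained.
#' @export
pretrain <- function(features, config = train_config(),
                     widths = c(1000, 800, 500, 100),
                     target = c("one_minus_auc", "neg_log10_ic50")) {
  target <- match.arg(target)
  y <- if (target == "one_minus_auc") features$y
  else features$extra$neg_log10_ic50 %||%
    stop2("feature table has no neg_log10_ic50 column")
  if (any(!is.finite(y))) stop2("non-finite training target")
  model <- build_network(ncol(features$x), head = "regression",
                         widths = widths, dropout = config$dropout,
                         seed = config$seed)
  model <- fit_network(model, features$x, y, config, groups = features$drug_id)
  model$provenance$pretrained <- TRUE
  model
}

#' @export
predict.sensitivity_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim)
    stop2("feature dimension mismatch: model expects ", object$input_dim,
          ", got ", ncol(newdata))
  forward_pass(object, newdata)$yhat
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat(sprintf("sensitivity_model (%s head): %d -> %s -> 1, %s parameters\n",
              x$head, x$input_dim, paste(x$widths, collapse = " -> "),
              format(n_params(x), big.mark = ",")))
  if (any(x$provenance$pretrained))
    cat("  pretrained layers:", paste(which(x$provenance$pretrained), collapse = ", "),
        "| frozen:", paste(which(x$provenance$frozen), collapse = ", "), "\n")
  if (!is.null(x$log))
    cat(sprintf("  trained %d epochs, best epoch %d\n", nrow(x$log), x$best_epoch))
  invisible(x)
}

#' @export
summary.sensitivity_model <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("  final train loss:", signif(utils::tail(object$log$train_loss, 1), 4))
    if (!all(is.na(object$log$val_loss)))
      cat(", best val loss:", signif(min(object$log$val_loss, na.rm = TRUE), 4))
    cat("\n")
  }
  invisible(object)
}

#' @method plot sensitivity_model
#' @export
plot.sensitivity_model <- function(x, ...) {
  if (is.null(x$log)) stop2("model has no training log")
  plot(x$log$epoch, x$log$train_loss, type = "l", xlab = "epoch",
       ylab = "loss", ...)
  if (!all(is.na(x$log$val_loss)))
    graphics::lines(x$log$epoch, x$log$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

encode_doubles <- function(v) jsonlite::base64_enc(writeBin(as.numeric(v), raw(), size = 8))
decode_doubles <- function(s, n) readBin(jsonlite::base64_dec(s), numeric(), n = n, size = 8)

#' Save a sensitivity model
#'
#' Writes a versioned JSON file with base64-encoded weight payloads; the
#' round-trip is bit-exact.
#'
#' @param model a `sensitivity_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  payload <- list(
    version = model$version, input_dim = model$input_dim,
    widths = model$widths, head = model$head, dropout = model$dropout,
    provenance = model$provenance, best_epoch = model$best_epoch %||% NA,
    log = model$log,
    layers = lapply(model$layers, function(l)
      list(dim = dim(l$W), W = encode_doubles(l$W), b = encode_doubles(l$b))))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Load a sensitivity model
#' @param path file written by [save_model()].
#' @return the `sensitivity_model`.
#' @export
load_model <- function(path) {
  p <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                   simplifyVector = FALSE),
                error = function(e) stop2("cannot parse model file: ", e$message))
  if (!identical(p$version, MODEL_FORMAT_VERSION))
    stop2("model format version mismatch: ", p$version %||% "<missing>")
  layers <- lapply(p$layers, function(l) {
    d <- unlist(l$dim)
    list(W = base::matrix(decode_doubles(l$W, d[1] * d[2]), d[1], d[2]),
         b = decode_doubles(l$b, d[2]))
  })
  prov <- do.call(rbind, lapply(p$provenance, as.data.frame))
  log <- if (is.null(p$log)) NULL
  else do.call(rbind, lapply(p$log, function(r)
    data.frame(epoch = r$epoch, train_loss = r$train_loss,
               val_loss = r$val_loss %||% NA_real_)))
  best <- p$best_epoch
  structure(list(input_dim = p$input_dim, widths = unlist(p$widths),
                 head = p$head, dropout = p$dropout, layers = layers,
                 provenance = prov, log = log,
                 best_epoch = if (is.null(best) || is.na(best)) NULL else best,
                 version = p$version),
            class = "sensitivity_model")
}
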