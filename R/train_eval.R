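#' Training configuration
#'
#' Hyperparameters of the CNN training loop. Defaults follow the published
#' run settings: RMSprop with learning rate 1e-4 and binary cross-entropy;
#' 25 epochs for the wavelet-feature network and 10 for the pixel network
#' (the hyperparameter tables' 80 / 30 are available as the
#' `epochs_preset` entries of the model specs). Batch size and the
#' train/validation split are not published; defaults 16 and 80/20.
#'
#' @param epochs integer >= 1.
#' @param learning_rate positive learning rate (default 1e-4).
#' @param batch_size mini-batch size (default 16).
#' @param validation_split fraction of samples held out for the validation
#'   curve (0 disables validation tracking).
#' @param seed integer seed controlling weight initialization, shuffling
#'   and dropout.
#' @return object of class `gw_train_config`.
#' @export
gw_train_config <- function(epochs = 25L, learning_rate = 1e-4,
                            batch_size = 16L, validation_split = 0.2,
                            seed = 1L) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(
    list(epochs = epochs, learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         validation_split = validation_split, seed = as.integer(seed)),
    class = "gw_train_config"
  )
}

#' Configuration for scaled-down demonstration runs
#'
#' The published configuration implies on the order of a thousand optimizer
#' updates (hundreds of slices, tens of epochs, batch 16). RMSprop's
#' per-parameter step is roughly the learning rate once its second-moment
#' estimate warms up, so what matters for a small run is the update count
#' times the learning rate. This preset keeps such runs on a comparable
#' optimization path: batch size 1 (plain stochastic gradient over tens of
#' slices) and the canonical RMSprop rate 1e-3, over at most 5 epochs. See
#' the methods vignette for the full argument.
#'
#' @param epochs epochs (default 5).
#' @param seed integer seed.
#' @return a [gw_train_config()].
#' @export
scaled_down_config <- function(epochs = 5L, seed = 1L) {
  gw_train_config(epochs = epochs, learning_rate = 1e-3, batch_size = 1L,
                  validation_split = 0, seed = seed)
}

#' Binary cross-entropy loss
#'
#' Mean over all elements of `-[t*log(p) + (1-t)*log(1-p)]`, with
#' predictions clipped to `[eps, 1 - eps]`.
#'
#' @param targets 0/1 values (vector or matrix, e.g. one-hot rows).
#' @param predictions probabilities, same shape as `targets`.
#' @param eps clipping constant, default 1e-7.
#' @return non-negative scalar.
#' @export
bce_loss <- function(targets, predictions, eps = 1e-7) {
  if (length(targets) != length(predictions)) {
    stop("targets and predictions must have the same shape", call. = FALSE)
  }
  t <- as.numeric(targets)
  p <- pmin(pmax(as.numeric(predictions), eps), 1 - eps)
  mean(-(t * log(p) + (1 - t) * log(1 - p)))
}

#' Train a CNN classifier
#'
#' Fits the network described by a [build_cnn1()] / [build_cnn2()]
#' specification on labeled feature tensors by mini-batch RMSprop on the
#' binary cross-entropy of the 2-unit sigmoid output over one-hot targets.
#' Deterministic given `config$seed`. Per-epoch loss and accuracy are
#' recorded for the training portion and, when `validation_split > 0`, a
#' held-out validation portion.
#'
#' @param spec a `gw_model_spec`.
#' @param x features: a 4D array (height, width, channels, samples) or a
#'   list of 3D arrays (height, width, channels), e.g. from
#'   [assemble_features()].
#' @param y 0/1 labels, one per sample; both classes must be present.
#' @param config a [gw_train_config()].
#' @return object of class `gw_cnn`: the fitted network, the config, and
#'   `curves` (data.frame epoch / train_loss / train_accuracy /
#'   val_loss / val_accuracy).
#' @export
gw_train <- function(spec, x, y, config = gw_train_config()) {
  stopifnot(inherits(spec, "gw_model_spec"),
            inherits(config, "gw_train_config"))
  x <- as_feature_array(x, spec$input_shape)
  y <- as.integer(as.logical(y))
  n <- dim(x)[4]
  if (length(y) != n) stop("labels do not match sample count", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  rng <- local_rng(config$seed)
  on.exit(rng(), add = TRUE)
  net <- init_network(spec, seed = sample.int(2^31 - 1L, 1L))
  state <- rmsprop_init(net)

  idx <- sample(n)
  n_val <- floor(config$validation_split * n)
  val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer()
  tr_idx <- setdiff(idx, val_idx)
  if (length(unique(y[tr_idx])) < 2L) {
    stop("training split lost a class; lower validation_split", call. = FALSE)
  }
  targets <- cbind(1 - y, y)  # one-hot: (negative, positive)

  curves <- data.frame(
    epoch = seq_len(config$epochs), train_loss = NA_real_,
    train_accuracy = NA_real_, val_loss = NA_real_, val_accuracy = NA_real_
  )
  for (ep in seq_len(config$epochs)) {
    order_ep <- sample(tr_idx)
    batches <- split(order_ep,
                     ceiling(seq_along(order_ep) / config$batch_size))
    for (bi in batches) {
      xb <- x[, , , bi, drop = FALSE]
      tb <- targets[bi, , drop = FALSE]
      fw <- nn_forward(net, xb, training = TRUE)
      # d(loss)/d(pre-activation) of sigmoid + elementwise BCE mean
      dpre <- (fw$out - tb) / length(tb)
      grads <- nn_backward(net, fw$caches, dpre)
      up <- rmsprop_update(net, grads, state, config$learning_rate)
      net <- up$net
      state <- up$state
    }
    eval_bs <- max(config$batch_size, 16L)
    ev <- nn_evaluate(net, x, targets, tr_idx, eval_bs)
    curves$train_loss[ep] <- ev$loss
    curves$train_accuracy[ep] <- ev$accuracy
    if (length(val_idx)) {
      ev <- nn_evaluate(net, x, targets, val_idx, eval_bs)
      curves$val_loss[ep] <- ev$loss
      curves$val_accuracy[ep] <- ev$accuracy
    }
  }
  structure(
    list(network = net, spec = spec, config = config, curves = curves,
         n_train = length(tr_idx), n_val = length(val_idx)),
    class = "gw_cnn"
  )
}

nn_evaluate <- function(net, x, targets, idx, batch_size) {
  loss_sum <- 0
  correct <- 0
  for (bi in split(idx, ceiling(seq_along(idx) / batch_size))) {
    out <- nn_forward(net, x[, , , bi, drop = FALSE], training = FALSE)$out
    tb <- targets[bi, , drop = FALSE]
    loss_sum <- loss_sum + bce_loss(tb, out) * length(bi)
    correct <- correct +
      sum(max.col(out, ties.method = "first") ==
            max.col(tb, ties.method = "first"))
  }
  list(loss = loss_sum / length(idx), accuracy = correct / length(idx))
}

as_feature_array <- function(x, input_shape) {
  if (is.list(x)) {
    d <- dims_of(x[[1]])
    if (length(d) == 2L) d <- c(d, 1L)
    arr <- array(0, dim = c(d, length(x)))
    for (i in seq_along(x)) arr[, , , i] <- x[[i]]
    x <- arr
  }
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) {
    stop("features must be a 4D array or list of 3D arrays", call. = FALSE)
  }
  if (!all(dim(x)[1:3] == input_shape)) {
    stop(sprintf("feature shape (%s) does not match model input (%s)",
                 paste(dim(x)[1:3], collapse = ","),
                 paste(input_shape, collapse = ",")), call. = FALSE)
  }
  x
}

#' @export
print.gw_cnn <- function(x, ...) {
  last <- x$curves[nrow(x$curves), ]
  cat(sprintf(
    "Fitted %s: %d epoch(s), %d training / %d validation samples\n",
    x$spec$name, x$config$epochs, x$n_train, x$n_val
  ))
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
              last$train_loss, last$train_accuracy))
  if (!is.na(last$val_loss)) {
    cat(sprintf("  final validation loss %.4f, accuracy %.3f\n",
                last$val_loss, last$val_accuracy))
  }
  invisible(x)
}

#' @export
summary.gw_cnn <- function(object, ...) {
  print(object)
  cat("\nArchitecture:\n")
  rep <- audit_model(object$spec, check = FALSE)
  print(rep, row.names = FALSE)
  invisible(object)
}

#' @export
#' @param type `"class"` for 0/1 labels (argmax), `"prob"` for the 2-column
#'   probability matrix (negative, positive).
#' @rdname gw_train
predict.gw_cnn <- function(object, x, type = c("class", "prob"),
                           batch_size = 32L, ...) {
  type <- match.arg(type)
  x <- as_feature_array(x, object$spec$input_shape)
  n <- dim(x)[4]
  out <- matrix(NA_real_, n, 2L)
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    out[bi, ] <- nn_forward(object$network, x[, , , bi, drop = FALSE],
                            training = FALSE)$out
  }
  if (type == "prob") out
  else as.integer(max.col(out, ties.method = "first") == 2L)
}

#' @export
plot.gw_cnn <- function(x, ...) {
  cv <- x$curves
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)), add = TRUE)
  graphics::plot(cv$epoch, cv$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = paste(x$spec$name, "loss"), ...)
  if (!all(is.na(cv$val_loss))) {
    graphics::lines(cv$epoch, cv$val_loss, lty = 2)
  }
  graphics::plot(cv$epoch, cv$train_accuracy, type = "l", xlab = "epoch",
                 ylab = "accuracy", ylim = c(0, 1),
                 main = paste(x$spec$name, "accuracy"), ...)
  if (!all(is.na(cv$val_accuracy))) {
    graphics::lines(cv$epoch, cv$val_accuracy, lty = 2)
  }
  invisible(x)
}

#' Disjoint k-fold partition of sample indices
#'
#' Splits `n` samples into `k` folds with sizes differing by at most one;
#' each fold serves once as the validation set while the remaining k-1
#' train.
#'
#' @param n number of samples (or a data.frame / vector, whose length is
#'   used).
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return list of `k` integer index vectors.
#' @export
kfold_split <- function(n, k = 5L, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  idx <- sample(n)
  split(idx, rep_len(seq_len(k), n))
}

#' Confusion counts of binary predictions
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return object of class `confusion_counts` with fields `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(as.logical(truth))
  predicted <- as.integer(as.logical(predicted))
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  structure(
    list(
      TP = sum(truth == 1L & predicted == 1L),
      TN = sum(truth == 0L & predicted == 0L),
      FP = sum(truth == 0L & predicted == 1L),
      FN = sum(truth == 1L & predicted == 0L)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Classification report from confusion counts
#'
#' Computes accuracy, sensitivity (recall), specificity, false negative
#' rate, false positive rate, precision and prevalence from TP/TN/FP/FN.
#' A metric with a zero denominator is reported as `NA` (undefined), never
#' as 0. Values are exact proportions; rounding is presentation-only (the
#' print method uses 2 decimals, half-up).
#'
#' @param counts a [confusion_counts()] object, or a list with TP, TN, FP,
#'   FN.
#' @return object of class `classification_report` (named list of
#'   proportions).
#' @export
classification_report <- function(counts) {
  TP <- counts$TP
  TN <- counts$TN
  FP <- counts$FP
  FN <- counts$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion table", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(
      accuracy = (TP + TN) / total,
      sensitivity = safe_div(TP, TP + FN),
      specificity = safe_div(TN, TN + FP),
      FNR = safe_div(FN, TP + FN),
      FPR = safe_div(FP, TN + FP),
      precision = safe_div(TP, TP + FP),
      prevalence = (TP + FN) / total,
      counts = list(TP = TP, TN = TN, FP = FP, FN = FN)
    ),
    class = "classification_report"
  )
}

# Half-up rounding to `digits` decimals (R's round() is banker's rounding).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.classification_report <- function(x, digits = 2L, ...) {
  nm <- c("accuracy", "sensitivity", "specificity", "FPR", "FNR", "precision")
  v <- vapply(x[nm], function(z) {
    if (is.na(z)) NA_real_ else round_half_up(z, digits)
  }, numeric(1))
  cat("classification report:\n")
  for (i in seq_along(nm)) {
    cat(sprintf("  %-12s %s\n", nm[i],
                ifelse(is.na(v[i]), "undefined", sprintf("%.2f", v[i]))))
  }
  cat(sprintf("  %-12s %.2f\n", "prevalence", x$prevalence))
  invisible(x)
}
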