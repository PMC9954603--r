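# Layer constructors for architecture specs. expected_shape /
# expected_params, when non-NULL, are asserted by audit_model().
layer_conv <- function(name, filters, kernel = c(3L, 3L),
                       padding = c("same", "valid"), activation = "relu",
                       expected_shape = NULL, expected_params = NULL) {
  padding <- match.arg(padding)
  list(name = name, kind = "convolution", filters = as.integer(filters),
       kernel = as.integer(kernel), padding = padding,
       activation = activation, expected_shape = expected_shape,
       expected_params = expected_params)
}

layer_maxpool <- function(name, pool = c(2L, 2L), expected_shape = NULL) {
  list(name = name, kind = "maxpool", pool = as.integer(pool),
       expected_shape = expected_shape, expected_params = 0L)
}

layer_dropout <- function(name, rate, expected_shape = NULL) {
  list(name = name, kind = "dropout", rate = rate,
       expected_shape = expected_shape, expected_params = 0L)
}

layer_flatten <- function(name = "Flatten", expected_shape = NULL) {
  list(name = name, kind = "flatten", expected_shape = expected_shape,
       expected_params = 0L)
}

layer_dense <- function(name, units, activation = "relu",
                        expected_shape = NULL, expected_params = NULL) {
  list(name = name, kind = "dense", units = as.integer(units),
       activation = activation, expected_shape = expected_shape,
       expected_params = expected_params)
}

new_model_spec <- function(name, input_shape, layers, hyperparameters) {
  structure(
    list(name = name, input_shape = as.integer(input_shape),
         layers = layers, hyperparameters = hyperparameters),
    class = "gw_model_spec"
  )
}

#' Pixel-intensity CNN architecture (CNN1)
#'
#' Builds the layer-by-layer specification of the 28-layer baseline network
#' operating on normalized 240x240 pixel intensities: six same-padding 3x3
#' convolutions (32, 32, 64, 64, 128, 128 filters) with dropout 0.3
#' interleaved and three 2x2 max-pools, then a dense head
#' 1024-512-512-128-64-2 with dropout 0.3 between layers. ReLU activations
#' throughout, sigmoid on the 2-unit output. Every layer carries the
#' published expected output shape and trainable parameter count, which
#' [audit_model()] verifies (e.g. flatten length 115,200 and first dense
#' layer 117,965,824 parameters).
#'
#' @return a `gw_model_spec`.
#' @export
build_cnn1 <- function() {
  dr <- 0.3
  layers <- list(
    layer_conv("Conv2D_1", 32L, expected_shape = c(240L, 240L, 32L),
               expected_params = 320L),
    layer_dropout("Dropout_1", dr, expected_shape = c(240L, 240L, 32L)),
    layer_conv("Conv2D_2", 32L, expected_shape = c(240L, 240L, 32L),
               expected_params = 9248L),
    layer_maxpool("MaxPool2D_1", expected_shape = c(120L, 120L, 32L)),
    layer_dropout("Dropout_2", dr, expected_shape = c(120L, 120L, 32L)),
    layer_conv("Conv2D_3", 64L, expected_shape = c(120L, 120L, 64L),
               expected_params = 18496L),
    layer_dropout("Dropout_3", dr, expected_shape = c(120L, 120L, 64L)),
    layer_conv("Conv2D_4", 64L, expected_shape = c(120L, 120L, 64L),
               expected_params = 36928L),
    layer_maxpool("MaxPool2D_2", expected_shape = c(60L, 60L, 64L)),
    layer_dropout("Dropout_4", dr, expected_shape = c(60L, 60L, 64L)),
    layer_conv("Conv2D_5", 128L, expected_shape = c(60L, 60L, 128L),
               expected_params = 73856L),
    layer_dropout("Dropout_5", dr, expected_shape = c(60L, 60L, 128L)),
    layer_conv("Conv2D_6", 128L, expected_shape = c(60L, 60L, 128L),
               expected_params = 147584L),
    layer_maxpool("MaxPool2D_3", expected_shape = c(30L, 30L, 128L)),
    layer_dropout("Dropout_6", dr, expected_shape = c(30L, 30L, 128L)),
    layer_flatten(expected_shape = 115200L),
    layer_dropout("Dropout_7", dr, expected_shape = 115200L),
    layer_dense("Dense_1", 1024L, expected_shape = 1024L,
                expected_params = 117965824),
    layer_dropout("Dropout_8", dr, expected_shape = 1024L),
    layer_dense("Dense_2", 512L, expected_shape = 512L,
                expected_params = 524800L),
    layer_dropout("Dropout_9", dr, expected_shape = 512L),
    layer_dense("Dense_3", 512L, expected_shape = 512L,
                expected_params = 262656L),
    layer_dropout("Dropout_10", dr, expected_shape = 512L),
    layer_dense("Dense_4", 128L, expected_shape = 128L,
                expected_params = 65664L),
    layer_dropout("Dropout_11", dr, expected_shape = 128L),
    layer_dense("Dense_5", 64L, expected_shape = 64L,
                expected_params = 8256L),
    layer_dropout("Dropout_12", dr, expected_shape = 64L),
    layer_dense("Dense_6", 2L, activation = "sigmoid",
                expected_shape = 2L, expected_params = 130L)
  )
  new_model_spec(
    "CNN1", c(240L, 240L, 1L), layers,
    list(optimizer = "rmsprop", learning_rate = 1e-4, epochs = 10L,
         epochs_preset = 30L, dropout_rate = dr,
         loss = "binary_crossentropy", batch_size = 16L)
  )
}

#' Wavelet-feature CNN architecture (CNN2)
#'
#' Builds the 17-layer network operating on the assembled 3-level Haar DWT
#' feature tensor: 3x3x32 same-padding convolution, 2x2 max-pool, 3x3x64
#' valid-padding convolution, 2x2 max-pool, dropout 0.2, flatten, dense head
#' 512-512-128-64-64-2 with dropout 0.2 between layers; ReLU activations and
#' a sigmoid 2-unit output. With the default input shape (1320, 15, 1) every
#' published output shape and parameter count is attached for
#' [audit_model()] (flatten 42,112; first dense layer 21,561,856). Other
#' input shapes (e.g. the stacked10 layout, 1200x120x1) are audited by the
#' same shape arithmetic without published expectations.
#'
#' @param input_shape integer (height, width, channels).
#' @return a `gw_model_spec`.
#' @export
build_cnn2 <- function(input_shape = c(1320L, 15L, 1L)) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L)
  # the valid conv needs >= 3 pixels in each spatial dim after the first pool
  if (input_shape[1] %/% 2L < 3L || input_shape[2] %/% 2L < 3L) {
    stop("input spatial dimensions too small for the valid convolution",
         call. = FALSE)
  }
  canonical <- all(input_shape == c(1320L, 15L, 1L))
  ex <- function(...) if (canonical) c(...) else NULL
  dr <- 0.2
  layers <- list(
    layer_conv("Conv2D_1", 32L, padding = "same",
               expected_shape = ex(1320L, 15L, 32L), expected_params = 320L),
    layer_maxpool("MaxPool2D_1", expected_shape = ex(660L, 7L, 32L)),
    layer_conv("Conv2D_2", 64L, padding = "valid",
               expected_shape = ex(658L, 5L, 64L), expected_params = 18496L),
    layer_maxpool("MaxPool2D_2", expected_shape = ex(329L, 2L, 64L)),
    layer_dropout("Dropout_1", dr, expected_shape = ex(329L, 2L, 64L)),
    layer_flatten(expected_shape = if (canonical) 42112L else NULL),
    layer_dense("Dense_1", 512L, expected_shape = 512L,
                expected_params = if (canonical) 21561856 else NULL),
    layer_dropout("Dropout_2", dr, expected_shape = 512L),
    layer_dense("Dense_2", 512L, expected_shape = 512L,
                expected_params = 262656L),
    layer_dropout("Dropout_3", dr, expected_shape = 512L),
    layer_dense("Dense_3", 128L, expected_shape = 128L,
                expected_params = 65664L),
    layer_dropout("Dropout_4", dr, expected_shape = 128L),
    layer_dense("Dense_4", 64L, expected_shape = 64L,
                expected_params = 8256L),
    layer_dropout("Dropout_5", dr, expected_shape = 64L),
    layer_dense("Dense_5", 64L, expected_shape = 64L,
                expected_params = 4160L),
    layer_dropout("Dropout_6", dr, expected_shape = 64L),
    layer_dense("Dense_6", 2L, activation = "sigmoid",
                expected_shape = 2L, expected_params = 130L)
  )
  new_model_spec(
    "CNN2", input_shape, layers,
    list(optimizer = "rmsprop", learning_rate = 1e-4, epochs = 25L,
         epochs_preset = 80L, dropout_rate = dr,
         loss = "binary_crossentropy", batch_size = 16L)
  )
}

#' @export
print.gw_model_spec <- function(x, ...) {
  cat(sprintf("%s architecture: input (%s), %d layers\n",
              x$name, paste(x$input_shape, collapse = ","),
              length(x$layers)))
  rep <- audit_model(x, check = FALSE)
  print(rep, row.names = FALSE)
  cat(sprintf("Total trainable parameters: %s\n",
              format(sum(rep$parameters), big.mark = ",")))
  invisible(x)
}

#' Structural audit of an architecture specification
#'
#' Walks the layer list computing the output shape and trainable parameter
#' count of every layer from first principles (convolution:
#' `filters * (kh * kw * in_channels + 1)`; dense: `in * units + units`;
#' pooling/dropout/flatten: 0) and, when `check = TRUE`, raises a detailed
#' error for any mismatch with the expected values attached to the spec.
#'
#' @param spec a `gw_model_spec`.
#' @param check assert expected shapes/parameter counts where present.
#' @return data.frame with columns `layer`, `kind`, `output_shape` (string),
#'   `parameters`.
#' @export
audit_model <- function(spec, check = TRUE) {
  stopifnot(inherits(spec, "gw_model_spec"))
  shape <- spec$input_shape
  rows <- vector("list", length(spec$layers))
  mismatches <- character()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    params <- 0
    shape <- switch(ly$kind,
      convolution = {
        stopifnot(length(shape) == 3L)
        params <- ly$filters *
          (ly$kernel[1] * ly$kernel[2] * shape[3] + 1)
        if (ly$padding == "same") {
          c(shape[1], shape[2], ly$filters)
        } else {
          h <- shape[1] - ly$kernel[1] + 1L
          w <- shape[2] - ly$kernel[2] + 1L
          if (h < 1L || w < 1L) {
            stop(sprintf("layer %s: input too small for valid convolution",
                         ly$name), call. = FALSE)
          }
          c(h, w, ly$filters)
        }
      },
      maxpool = c(shape[1] %/% ly$pool[1], shape[2] %/% ly$pool[2], shape[3]),
      dropout = shape,
      flatten = prod(shape),
      dense = {
        stopifnot(length(shape) == 1L)
        params <- shape * ly$units + ly$units
        ly$units
      },
      stop(sprintf("unknown layer kind '%s'", ly$kind), call. = FALSE)
    )
    if (check && !is.null(ly$expected_shape) &&
        !identical(as.numeric(shape), as.numeric(ly$expected_shape))) {
      mismatches <- c(mismatches, sprintf(
        "layer %s: expected shape (%s), audited (%s)",
        ly$name, paste(ly$expected_shape, collapse = ","),
        paste(shape, collapse = ",")
      ))
    }
    if (check && !is.null(ly$expected_params) &&
        !isTRUE(all.equal(as.numeric(params),
                          as.numeric(ly$expected_params)))) {
      mismatches <- c(mismatches, sprintf(
        "layer %s: expected %s parameters, audited %s",
        ly$name, format(ly$expected_params, big.mark = ","),
        format(params, big.mark = ",")
      ))
    }
    rows[[i]] <- data.frame(
      layer = ly$name, kind = ly$kind,
      output_shape = paste(shape, collapse = "x"),
      parameters = as.numeric(params),
      stringsAsFactors = FALSE
    )
  }
  if (length(mismatches)) {
    stop(paste(c("architecture audit failed:", mismatches), collapse = "\n  "),
         call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Flatten a square slice to a row-major pixel feature vector
#'
#' @param slice a `labeled_slice` or numeric matrix (square).
#' @return numeric vector of length `side^2`, rows concatenated in order.
#' @export
flatten_pixels <- function(slice) {
  px <- slice_pixels(slice)
  if (nrow(px) != ncol(px)) stop("expected a square slice", call. = FALSE)
  as.numeric(t(px))
}

#' Grid search for the SVM baseline
#'
#' Selects the cost `C` and kernel of a kernel SVM by k-fold cross-validated
#' accuracy on standardized features. Ties are broken toward the smaller
#' `C`, then by kernel order linear < radial < polynomial < sigmoid.
#' Deterministic for a fixed seed. The winning configuration is refitted on
#' all data.
#'
#' @param features numeric matrix (samples x features), already
#'   standardized.
#' @param labels 0/1 vector, both classes present with at least `folds`
#'   samples each.
#' @param C_grid numeric vector of cost values; the default includes the
#'   published optimum 0.7.
#' @param kernels subset of `c("linear", "radial", "polynomial",
#'   "sigmoid")`.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return object of class `gw_svm`: the selected `C`, `kernel`, the CV
#'   accuracy table, and the refitted `e1071::svm` model.
#' @export
svm_grid_search <- function(features, labels,
                            C_grid = c(0.1, 0.5, 0.7, 1, 2),
                            kernels = c("linear", "radial", "polynomial",
                                        "sigmoid"),
                            folds = 10L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  if (min(table(labels)) < folds) {
    stop("need at least `folds` samples per class", call. = FALSE)
  }
  kernels <- match.arg(kernels, several.ok = TRUE)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  fold_id <- stratified_folds(labels, folds)
  grid <- expand.grid(C = C_grid, kernel = kernels,
                      stringsAsFactors = FALSE)
  grid$cv_accuracy <- NA_real_
  y <- factor(labels, levels = c(0L, 1L))
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- e1071::svm(features[tr, , drop = FALSE], y[tr],
                        kernel = grid$kernel[g], cost = grid$C[g],
                        scale = FALSE)
      pred <- stats::predict(fit, features[!tr, , drop = FALSE])
      acc[f] <- mean(pred == y[!tr])
    }
    grid$cv_accuracy[g] <- mean(acc)
  }
  kernel_rank <- match(grid$kernel,
                       c("linear", "radial", "polynomial", "sigmoid"))
  ord <- order(-grid$cv_accuracy, grid$C, kernel_rank)
  best <- grid[ord[1L], ]
  model <- e1071::svm(features, y, kernel = best$kernel, cost = best$C,
                      scale = FALSE)
  structure(
    list(C = best$C, kernel = best$kernel,
         cv_accuracy = best$cv_accuracy, grid = grid, model = model,
         feature_length = ncol(features)),
    class = "gw_svm"
  )
}

stratified_folds <- function(labels, k) {
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold_id
}

#' @export
print.gw_svm <- function(x, ...) {
  cat(sprintf(
    "SVM baseline: kernel = %s, C = %g (CV accuracy %.3f, %d features)\n",
    x$kernel, x$C, x$cv_accuracy, x$feature_length
  ))
  invisible(x)
}

#' @export
predict.gw_svm <- function(object, newdata, ...) {
  as.integer(as.character(stats::predict(object$model, as.matrix(newdata))))
}
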