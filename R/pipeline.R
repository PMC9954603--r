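#' Column standardizer for flat feature matrices
#'
#' Per-feature mean/sd from a training matrix, reusable at test time.
#' Zero-variance features map to zero.
#'
#' @param x numeric matrix (samples x features).
#' @return object of class `feature_standardizer`.
#' @export
feature_standardizer <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  structure(list(mean = mu, sd = sdv), class = "feature_standardizer")
}

#' @rdname feature_standardizer
#' @param object a `feature_standardizer`.
#' @param newdata matrix to standardize.
#' @param ... unused.
#' @export
predict.feature_standardizer <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- sweep(newdata, 2L, object$mean, `-`)
  sdv <- ifelse(object$sd > 0, object$sd, 1)
  out <- sweep(out, 2L, sdv, `/`)
  out[, object$sd == 0] <- 0
  out
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates a seeded phantom dataset, preprocesses it (skull stripping
#' where a skull is present), extracts features, trains the wavelet-feature
#' CNN and the requested baselines, evaluates every model on the held-out
#' test split, and runs the paired comparison between the first two models.
#' Everything is reproducible from `seed`; if `out_dir` is given, the
#' manifest (CSV), a config snapshot and the reports (JSON) are written
#' there.
#'
#' @param n_per_class named integer vector of training slices per class
#'   (test split gets half as many, at least 5). Default 20 gliomas and 20
#'   non-pathological slices — a small, clearly separable task.
#' @param models character vector among `"cnn2_dwt"` (wavelet-feature CNN),
#'   `"svm_pixels"` (kernel SVM on flattened pixels), `"svm_dwt"` (SVM on
#'   the raveled 3-level wavelet pyramid) and `"cnn1_pixels"` (the large
#'   pixel CNN; computationally heavy). The first two are the default.
#' @param epochs training epochs for the CNNs.
#' @param layout feature layout for the wavelet CNN (see
#'   [assemble_features()]).
#' @param svm_C_grid,svm_kernels,svm_folds grid-search settings forwarded
#'   to [svm_grid_search()] for the SVM baselines (the full default grid is
#'   expensive at 57,600 features; small demonstration runs may restrict
#'   it).
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param verbose print one line per stage.
#' @return list with `manifest`, per-model `reports`
#'   ([classification_report()] objects), `contingency` and `comparison`
#'   (first model pair), and `config`.
#' @export
run_pipeline <- function(n_per_class = c(glioma = 20L, non_pathological = 20L),
                         models = c("cnn2_dwt", "svm_pixels"),
                         epochs = 5L, layout = "compat1320x15",
                         svm_C_grid = c(0.1, 0.5, 0.7, 1, 2),
                         svm_kernels = c("linear", "radial", "polynomial",
                                         "sigmoid"),
                         svm_folds = 10L, seed = 1L,
                         out_dir = NULL, verbose = TRUE) {
  models <- match.arg(models,
                      c("cnn2_dwt", "svm_pixels", "svm_dwt", "cnn1_pixels"),
                      several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  config <- list(n_per_class = as.list(n_per_class), models = models,
                 epochs = epochs, layout = layout, seed = seed,
                 package_version = as.character(utils::packageVersion("gliowave")))

  comp <- data.frame(
    class = names(n_per_class),
    train = as.integer(n_per_class),
    test = pmax(5L, as.integer(n_per_class) %/% 2L)
  )
  manifest <- generate_dataset(comp, seed = seed)
  say("generate: %d train / %d test slices", sum(manifest$split == "train"),
      sum(manifest$split == "test"))

  slices <- lapply(seq_len(nrow(manifest)), function(i) {
    s <- manifest_slice(manifest, i)
    if (manifest$has_skull[i]) s <- skull_strip(s)$slice
    s
  })
  say("preprocess: skull stripping applied to %d slice(s)",
      sum(manifest$has_skull))

  tr <- which(manifest$split == "train")
  te <- which(manifest$split == "test")
  y_tr <- manifest$label[tr]
  y_te <- manifest$label[te]

  preds <- list()
  fits <- list()
  for (m in models) {
    if (m == "cnn2_dwt") {
      pyr_tr <- lapply(slices[tr], function(s) haar_pyramid(s$pixels, 3L))
      pyr_te <- lapply(slices[te], function(s) haar_pyramid(s$pixels, 3L))
      stats <- dwt_standardizer(pyr_tr)
      x_tr <- lapply(pyr_tr, assemble_features, layout = layout,
                     stats = stats)
      x_te <- lapply(pyr_te, assemble_features, layout = layout,
                     stats = stats)
      spec <- build_cnn2(dims_of(x_tr[[1]]))
      fit <- gw_train(spec, x_tr, y_tr,
                      scaled_down_config(epochs = epochs, seed = seed + 1L))
      say("train %s: final training accuracy %.3f", m,
          utils::tail(fit$curves$train_accuracy, 1))
      preds[[m]] <- predict(fit, x_te)
      fits[[m]] <- fit
    } else if (m == "cnn1_pixels") {
      x_tr <- lapply(slices[tr], function(s)
        normalize_intensities(s$pixels))
      x_te <- lapply(slices[te], function(s)
        normalize_intensities(s$pixels))
      to3 <- function(l) lapply(l, function(px) array(px, c(dim(px), 1L)))
      spec <- build_cnn1()
      fit <- gw_train(spec, to3(x_tr), y_tr,
                      scaled_down_config(epochs = epochs, seed = seed + 2L))
      say("train %s: final training accuracy %.3f", m,
          utils::tail(fit$curves$train_accuracy, 1))
      preds[[m]] <- predict(fit, to3(x_te))
      fits[[m]] <- fit
    } else {
      feat <- function(s) {
        if (m == "svm_pixels") {
          flatten_pixels(s$pixels)
        } else {
          pyr <- haar_pyramid(s$pixels, 3L)
          unlist(pyramid_subband_list(pyr), use.names = FALSE)
        }
      }
      f_tr <- do.call(rbind, lapply(slices[tr], feat))
      f_te <- do.call(rbind, lapply(slices[te], feat))
      std <- feature_standardizer(f_tr)
      folds <- max(2L, min(svm_folds, min(table(y_tr))))
      fit <- svm_grid_search(predict(std, f_tr), y_tr, C_grid = svm_C_grid,
                             kernels = svm_kernels, folds = folds,
                             seed = seed + 3L)
      say("train %s: selected kernel %s, C = %g", m, fit$kernel, fit$C)
      preds[[m]] <- predict(fit, predict(std, f_te))
      fits[[m]] <- fit
    }
  }

  reports <- lapply(preds, function(p)
    classification_report(confusion_counts(y_te, p)))
  contingency <- NULL
  comparison <- NULL
  if (length(models) >= 2L) {
    contingency <- paired_contingency(preds[[1]] == y_te, preds[[2]] == y_te)
    comparison <- tryCatch(compare_classifiers(contingency),
                           error = function(e) list(error = conditionMessage(e)))
    say("compare %s vs %s: discordant b = %d, c = %d", models[1], models[2],
        contingency$b, contingency$c)
  }

  out <- list(manifest = manifest, fits = fits, predictions = preds,
              reports = reports, contingency = contingency,
              comparison = comparison, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    rep_json <- lapply(reports, function(r) r[setdiff(names(r), "counts")])
    jsonlite::write_json(
      list(reports = rep_json,
           contingency = if (!is.null(contingency))
             contingency[c("a", "b", "c", "d", "N")],
           pearson = if (!is.null(comparison$pearson))
             format_report(comparison$pearson)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA
    )
  }
  out
}
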