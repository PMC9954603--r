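#' Published reference confusion counts of the five classifiers
#'
#' The confusion cells (TP/TN/FP/FN on the shared 190-slice test set)
#' reported by the glioma-classification study this package's methods
#' derive from, used here as fixed inputs for validating the metric suite
#' and the comparison statistics. Note the published report rows are not
#' all arithmetically consistent with these cells; this package always
#' recomputes metrics from the counts.
#'
#' @return data.frame with columns `model`, `TP`, `TN`, `FP`, `FN`.
#' @export
reference_confusion <- function() {
  data.frame(
    model = c("CNN-DWT", "CNN", "SVM-DWT", "SVM", "CNN-TL-VGG16"),
    TP = c(100L, 95L, 84L, 67L, 74L),
    TN = c(78L, 84L, 61L, 106L, 92L),
    FP = c(6L, 0L, 0L, 17L, 17L),
    FN = c(6L, 11L, 45L, 0L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Published paired contingency tables for classifier comparison
#'
#' The two published correct/incorrect cross-tables: the wavelet-feature
#' CNN against the pixel CNN (cells 100, 6, 11, 95; N = 212) and the
#' wavelet-feature SVM against the pixel SVM (cells 84, 0, 45, 67;
#' N = 196). Used as fixed inputs to the comparison statistics.
#'
#' @param pair `"cnn"` or `"svm"`.
#' @return a [paired_contingency()].
#' @export
reference_paired_table <- function(pair = c("cnn", "svm")) {
  pair <- match.arg(pair)
  if (pair == "cnn") {
    new_paired_contingency(a = 100L, b = 6L, c = 11L, d = 95L)
  } else {
    new_paired_contingency(a = 84L, b = 0L, c = 45L, d = 67L)
  }
}
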