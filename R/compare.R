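#' Paired 2x2 contingency table of two classifiers
#'
#' Cross-tabulates the per-sample correctness of two classifiers evaluated
#' on the same test set: `a` both correct, `b` model 1 correct and model 2
#' wrong, `c` model 1 wrong and model 2 correct, `d` both wrong. `b` and
#' `c` form the discordant pair.
#'
#' @param outcomes1,outcomes2 logical (or 0/1) vectors of equal length:
#'   whether each model classified each sample correctly.
#' @return object of class `paired_contingency` with fields `a`, `b`, `c`,
#'   `d` and `N`.
#' @export
paired_contingency <- function(outcomes1, outcomes2) {
  o1 <- as.logical(outcomes1)
  o2 <- as.logical(outcomes2)
  if (length(o1) != length(o2)) {
    stop("outcome vectors must have equal length", call. = FALSE)
  }
  new_paired_contingency(
    a = sum(o1 & o2), b = sum(o1 & !o2), c = sum(!o1 & o2), d = sum(!o1 & !o2)
  )
}

#' @rdname paired_contingency
#' @param a,b,c,d non-negative cell counts.
#' @export
new_paired_contingency <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d),
            class = "paired_contingency")
}

#' @export
print.paired_contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("model1 correct", "model1 wrong"),
                              c("model2 correct", "model2 wrong")))
  cat(sprintf("paired contingency (N = %d):\n", x$N))
  print(m)
  invisible(x)
}

new_comparison_result <- function(statistic, df, N, p_value, method,
                                  alpha = 0.05, note = NULL) {
  structure(
    list(statistic = statistic, df = df, N = N, p_value = p_value,
         method = method, alpha = alpha,
         significant = is.finite(p_value) && p_value < alpha, note = note),
    class = "comparison_result"
  )
}

#' Pearson chi-squared independence test on the paired table
#'
#' The uncorrected Pearson statistic
#' `N * (a*d - b*c)^2 / ((a+b) * (c+d) * (a+c) * (b+d))` with 1 degree of
#' freedom on the correct/incorrect cross-table of two classifiers. This is
#' the statistic that reproduces the published comparison value 149.7861 on
#' the CNN pair's table; note it tests independence of the two correctness
#' margins, not marginal homogeneity (see [mcnemar_edwards()] for the
#' paired test proper).
#'
#' @param table a [paired_contingency()].
#' @param alpha significance threshold (default 0.05).
#' @return object of class `comparison_result`.
#' @export
pearson_chi2 <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "paired_contingency"))
  a <- table$a
  b <- table$b
  c <- table$c
  d <- table$d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  stat <- table$N * (a * d - b * c)^2 / prod(margins)
  new_comparison_result(stat, 1L, table$N,
                        stats::pchisq(stat, 1L, lower.tail = FALSE),
                        "pearson_chi2", alpha)
}

#' Edwards-corrected McNemar test
#'
#' Continuity-corrected McNemar statistic on the discordant counts:
#' `(|b - c| - 1)^2 / (b + c)`, 1 degree of freedom, p-value from the
#' chi-squared survival function. When `b + c < 25` the chi-squared
#' approximation is unreliable and the result carries a `"small-sample"`
#' note (use [exact_binomial_p()] instead).
#'
#' @param b,c discordant counts (model 1 correct/model 2 wrong, and the
#'   reverse). A `paired_contingency` may be given as `b`.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `comparison_result`.
#' @export
mcnemar_edwards <- function(b, c = NULL, alpha = 0.05) {
  if (inherits(b, "paired_contingency")) {
    c <- b$c
    N <- b$N
    b <- b$b
  } else {
    N <- b + c
  }
  if (b + c == 0) stop("no discordant pairs", call. = FALSE)
  stat <- (abs(b - c) - 1)^2 / (b + c)
  new_comparison_result(
    stat, 1L, N, stats::pchisq(stat, 1L, lower.tail = FALSE),
    "mcnemar_edwards", alpha,
    note = if (b + c < 25) "small-sample" else NULL
  )
}

#' Exact binomial McNemar p-value
#'
#' Two-sided exact p for the discordant pair under the null that either
#' model is equally likely to win a disagreement:
#' `p = min(1, 2 * P(X >= max(b, c)))` with `X ~ Binomial(b + c, 1/2)`.
#'
#' @inheritParams mcnemar_edwards
#' @return p-value in (0, 1].
#' @export
exact_binomial_p <- function(b, c = NULL) {
  if (inherits(b, "paired_contingency")) {
    c <- b$c
    b <- b$b
  }
  n <- b + c
  if (n < 1) stop("need at least one discordant pair", call. = FALSE)
  k <- max(b, c)
  min(1, 2 * stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

#' Compare two classifiers on one test set
#'
#' Convenience wrapper running all three comparison procedures on the
#' paired table: the Pearson independence chi-squared (the statistic the
#' published tables print), the Edwards-corrected McNemar test, and the
#' exact binomial p.
#'
#' @param table a [paired_contingency()].
#' @param alpha significance threshold.
#' @return list with elements `pearson`, `mcnemar`, `exact_p`. The
#'   comparison is reported per-pair without multiple-testing correction.
#' @export
compare_classifiers <- function(table, alpha = 0.05) {
  list(
    pearson = pearson_chi2(table, alpha),
    mcnemar = mcnemar_edwards(table, alpha = alpha),
    exact_p = exact_binomial_p(table)
  )
}

#' Format a comparison result for reporting
#'
#' Renders the conventional string
#' `"X^2 (df, N = n) = stat, p-value = p"` with the statistic to 4
#' decimals; p-values below 1e-5 render as `"p-value < 0.00001"`.
#'
#' @param result a `comparison_result`.
#' @return character scalar.
#' @export
format_report <- function(result) {
  stopifnot(inherits(result, "comparison_result"))
  p <- result$p_value
  ptxt <- if (p < 1e-5) "p-value < 0.00001"
          else sprintf("p-value = %.5f", p)
  sprintf("X^2 (%d, N = %d) = %.4f, %s", result$df, result$N,
          result$statistic, ptxt)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$method, format_report(x),
              if (!is.null(x$note)) sprintf(" [%s]", x$note) else ""))
  cat(sprintf("  %s at alpha = %g\n",
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}
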