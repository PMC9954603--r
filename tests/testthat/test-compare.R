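test_that("paired contingency cells count agreement patterns", {
  o1 <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  o2 <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  tab <- paired_contingency(o1, o2)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 2, b = 1, c = 1, d = 1))
  same <- paired_contingency(o1, o1)
  expect_equal(same$b + same$c, 0)
  opp <- paired_contingency(o1, !o1)
  expect_equal(opp$a + opp$d, 0)
  expect_error(paired_contingency(o1, o2[-1]), "equal length")
})

test_that("Pearson chi-squared reproduces the published CNN-pair statistic", {
  r <- pearson_chi2(reference_paired_table("cnn"))
  expect_equal(round(r$statistic, 4), 149.7861)
  expect_equal(r$df, 1L)
  expect_equal(r$N, 212L)
  expect_lt(r$p_value, 1e-5)
  # independent oracle: stats::chisq.test without continuity correction
  m <- matrix(c(100, 11, 6, 95), 2, 2)
  expect_equal(r$statistic,
               unname(stats::chisq.test(m, correct = FALSE)$statistic))
})

test_that("Pearson statistic on the SVM-pair printed cells follows the closed form", {
  r <- pearson_chi2(reference_paired_table("svm"))
  # closed form: 196 * (84*67 - 0*45)^2 / (84 * 112 * 129 * 67)
  expect_equal(r$statistic, 6208179264 / 81313344)
  expect_equal(round(r$statistic, 3), 76.349)
  m <- matrix(c(84, 45, 0, 67), 2, 2)
  expect_equal(r$statistic,
               unname(stats::chisq.test(m, correct = FALSE)$statistic))
})

test_that("Pearson statistic is invariant under transposition, row swap, and independence", {
  tab <- new_paired_contingency(30, 12, 7, 41)
  s0 <- pearson_chi2(tab)$statistic
  expect_equal(pearson_chi2(new_paired_contingency(30, 7, 12, 41))$statistic,
               s0)  # transpose
  expect_equal(pearson_chi2(new_paired_contingency(7, 41, 30, 12))$statistic,
               s0)  # swap the two models (rows)
  expect_equal(pearson_chi2(new_paired_contingency(10, 10, 20, 20))$statistic,
               0)
  expect_error(pearson_chi2(new_paired_contingency(5, 5, 0, 0)), "margin")
})

test_that("Edwards-corrected McNemar follows its formula and flags small samples", {
  r <- mcnemar_edwards(6, 11)
  expect_equal(r$statistic, (abs(6 - 11) - 1)^2 / 17)
  expect_equal(round(r$statistic, 4), 0.9412)
  expect_identical(r$note, "small-sample")
  expect_equal(mcnemar_edwards(5, 5)$statistic, 0.1)
  expect_null(mcnemar_edwards(20, 20)$note)
  expect_error(mcnemar_edwards(0, 0), "discordant")
  # symmetric in (b, c); oracle: stats::mcnemar.test with correction
  expect_equal(mcnemar_edwards(6, 11)$statistic,
               mcnemar_edwards(11, 6)$statistic)
  m <- matrix(c(50, 11, 6, 50), 2, 2)
  expect_equal(mcnemar_edwards(6, 11)$statistic,
               unname(stats::mcnemar.test(m)$statistic))
})

test_that("exact binomial p matches tail sums and clamps at one", {
  expect_equal(exact_binomial_p(3, 0), 0.25)  # 2 * 0.5^3
  expect_equal(exact_binomial_p(1, 1), 1.0)   # 2 * P(X >= 1) clamped
  # oracle: binom.test two-sided is equivalent at b = c + k for symmetric null
  expect_equal(exact_binomial_p(9, 2),
               stats::binom.test(9, 11, 0.5)$p.value, tolerance = 1e-12)
  expect_error(exact_binomial_p(0, 0), "discordant|at least one")
})

test_that("exact p is monotone in the imbalance and within (0, 1]", {
  n <- 30L
  prev <- Inf
  for (b in 15:25) {
    p <- exact_binomial_p(b, n - b)
    expect_true(p > 0 && p <= 1)
    expect_lte(p, prev + 1e-12)
    prev <- p
  }
})

test_that("exact and Edwards p-values agree for large discordant counts", {
  set.seed(12)
  for (rep in 1:50) {
    bc <- sample(50:200, 1L)
    b <- stats::rbinom(1L, bc, 0.5)
    c <- bc - b
    if (b == c) next  # degenerate: exact two-sided p is identically 1
    pe <- exact_binomial_p(b, c)
    pm <- mcnemar_edwards(b, c)$p_value
    expect_lt(abs(pe - pm), 0.02,
              label = sprintf("b=%d c=%d exact=%.4f edwards=%.4f",
                              b, c, pe, pm))
  }
})

test_that("reports render in the conventional chi-squared format", {
  r <- pearson_chi2(reference_paired_table("cnn"))
  expect_equal(format_report(r),
               "X^2 (1, N = 212) = 149.7861, p-value < 0.00001")
  z <- pearson_chi2(new_paired_contingency(10, 10, 20, 20))
  expect_match(format_report(z), "= 0.0000, p-value = 1.00000", fixed = TRUE)
})

test_that("compare_classifiers bundles the three procedures consistently", {
  tab <- reference_paired_table("cnn")
  res <- compare_classifiers(tab)
  expect_equal(res$pearson$method, "pearson_chi2")
  expect_equal(res$mcnemar$method, "mcnemar_edwards")
  expect_equal(res$exact_p,
               exact_binomial_p(tab$b, tab$c))
})
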