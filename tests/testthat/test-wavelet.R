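test_that("haar_step matches direct evaluation of the block formulas", {
  s <- haar_step(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(s$LL, matrix(10, 1, 1))
  expect_equal(s$LH, matrix(4, 1, 1))
  expect_equal(s$HL, matrix(2, 1, 1))
  expect_equal(s$HH, matrix(0, 1, 1))

  set.seed(11)
  for (n in c(4L, 6L, 10L)) {
    img <- random_even_matrix(n, n + 2L)
    got <- haar_step(img)
    want <- haar_step_loop_oracle(img)
    expect_equal(got$LL, want$LL)
    expect_equal(got$LH, want$LH)
    expect_equal(got$HL, want$HL)
    expect_equal(got$HH, want$HH)
  }
})

test_that("difference sub-bands annihilate constants and sides halve", {
  s <- haar_step(matrix(7, 8, 8))
  expect_true(all(s$LL == 28))
  expect_true(all(s$LH == 0) && all(s$HL == 0) && all(s$HH == 0))
  s240 <- haar_step(matrix(0, 240, 240))
  expect_equal(dim(s240$LL), c(120L, 120L))
  expect_error(haar_step(matrix(0, 3, 4)), "even")
})

test_that("inverse_haar_step inverts exactly on integer grids", {
  s <- list(LL = matrix(10, 1, 1), LH = matrix(4, 1, 1),
            HL = matrix(2, 1, 1), HH = matrix(0, 1, 1))
  expect_equal(inverse_haar_step(s), matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(
    inverse_haar_step(list(LL = matrix(0, 3, 3), LH = matrix(0, 3, 3),
                           HL = matrix(0, 3, 3), HH = matrix(0, 3, 3))),
    matrix(0, 6, 6)
  )
  set.seed(21)
  for (rep in 1:5) {
    img <- random_even_matrix(12L)
    expect_identical(inverse_haar_step(haar_step(img)), img * 1.0)
  }
  expect_error(
    inverse_haar_step(list(LL = matrix(0, 2, 2), LH = matrix(0, 1, 1),
                           HL = matrix(0, 2, 2), HH = matrix(0, 2, 2))),
    "mismatch"
  )
})

test_that("pyramid reconstruction is exact for P in 1..3 on integer grids", {
  set.seed(31)
  img <- random_even_matrix(48L)
  for (p in 1:3) {
    pyr <- haar_pyramid(img, p)
    expect_identical(haar_reconstruct(pyr), img * 1.0)
  }
  expect_equal(haar_pyramid(img, 1L)$details[[1]]$horizontal,
               haar_step(img)$LH)
  expect_error(haar_pyramid(random_even_matrix(20L), 3L), "divisible")
})

test_that("a 3-level pyramid of a 240x240 slice has 10 sub-bands with the halving shape law", {
  img <- matrix(stats::runif(240^2), 240, 240)
  pyr <- haar_pyramid(img, 3L)
  expect_equal(dim(pyr$approximation), c(30L, 30L))
  bands <- c(list(pyr$approximation),
             unlist(pyr$details, recursive = FALSE, use.names = FALSE))
  expect_length(bands, 10L)
  for (k in 1:3) {
    for (d in pyr$details[[k]]) expect_equal(dim(d), c(240L, 240L) / 2^k)
  }
  # total coefficient count equals the input pixel count
  expect_equal(sum(vapply(bands, length, numeric(1))), 240^2)
})

test_that("orthonormal scaling conserves energy to 1e-9 relative", {
  set.seed(41)
  img <- matrix(stats::rnorm(96^2, 100, 30), 96, 96)
  for (p in 1:3) {
    pyr <- haar_pyramid(img, p, normalization = "orthonormal")
    e_coeff <- sum(pyr$approximation^2) +
      sum(vapply(pyr$details, function(d) sum(unlist(d)^2), numeric(1)))
    expect_lt(abs(e_coeff - sum(img^2)) / sum(img^2), 1e-9)
  }
})

test_that("the transform is linear in the input", {
  set.seed(51)
  x <- random_even_matrix(16L)
  y <- random_even_matrix(16L)
  a <- 2.5
  b <- -1.25
  pa <- haar_pyramid(a * x + b * y, 2L)
  px <- haar_pyramid(x, 2L)
  py <- haar_pyramid(y, 2L)
  expect_equal(pa$approximation, a * px$approximation + b * py$approximation)
  for (k in 1:2) {
    for (nm in names(pa$details[[k]])) {
      expect_equal(pa$details[[k]][[nm]],
                   a * px$details[[k]][[nm]] + b * py$details[[k]][[nm]])
    }
  }
})

test_that("haar_step agrees with the PyWavelets oracle on random even grids", {
  py <- pywt_haar_oracle(diag(4))
  skip_if(is.null(py), "python/pywt oracle unavailable")
  set.seed(61)
  for (rep in 1:50) {
    n <- 2L * sample(2:12, 1L)
    m <- 2L * sample(2:12, 1L)
    img <- random_even_matrix(n, m, integers = sample(c(TRUE, FALSE), 1L))
    ours <- haar_step(img, normalization = "orthonormal")
    ref <- pywt_haar_oracle(img)
    # sign conventions differ for the detail filters
    expect_equal(ours$LL, ref$cA, tolerance = 1e-10)
    expect_equal(ours$LH, -ref$cH, tolerance = 1e-10)
    expect_equal(ours$HL, -ref$cV, tolerance = 1e-10)
    expect_equal(ours$HH, ref$cD, tolerance = 1e-10)
  }
})

test_that("pad_to appends zeros bottom/right leaving values untouched", {
  set.seed(71)
  m <- matrix(stats::rnorm(60 * 60), 60, 60)
  p <- pad_to(m, 120L)
  expect_equal(dim(p), c(120L, 120L))
  expect_equal(p[1:60, 1:60], m)
  expect_true(all(p[61:120, ] == 0) && all(p[, 61:120] == 0))
  expect_equal(sum(p), sum(m))
  expect_identical(pad_to(m, 60L), m)
  expect_error(pad_to(m, 30L), "larger")
})

test_that("assemble_features produces the documented layouts", {
  set.seed(81)
  img <- matrix(stats::runif(240^2, 0, 255), 240, 240)
  pyr <- haar_pyramid(img, 3L)
  f10 <- assemble_features(pyr, "stacked10")
  expect_equal(dim(f10), c(1200L, 120L, 1L))
  fp <- assemble_features(pyr, "compat1320x15")
  expect_equal(dim(fp), c(1320L, 15L, 1L))
  # the compatibility layout is a row-major re-slicing of the same ravel
  expect_equal(as.numeric(t(fp[, , 1])),
               as.numeric(t(f10[, , 1]))[seq_len(1320 * 15)])
  # per-sub-band z-scoring: the 30x30 approximation block of the stack
  a3 <- f10[1:30, 1:30, 1]
  expect_equal(mean(a3), 0, tolerance = 1e-8)
  expect_equal(stats::sd(as.numeric(a3)), 1, tolerance = 1e-8)
  # padded regions are exactly zero
  expect_true(all(f10[1:30, 31:120, 1] == 0))

  # all-zero image maps to an all-zero tensor (zero-variance guard)
  z <- assemble_features(haar_pyramid(matrix(0, 240, 240), 3L), "stacked10")
  expect_true(all(z == 0))
  expect_error(assemble_features(haar_pyramid(img, 2L)), "3-level")
})

test_that("persisted standardizer statistics are reused at test time", {
  set.seed(91)
  pyrs <- lapply(1:4, function(i) {
    haar_pyramid(matrix(stats::runif(240^2, 0, 255), 240, 240), 3L)
  })
  a3 <- pyrs[[4]]$approximation

  st_band <- dwt_standardizer(pyrs[1:3], scope = "subband")
  f <- assemble_features(pyrs[[4]], "stacked10", stats = st_band)
  want <- (a3 - st_band$stats$A$mean) / st_band$stats$A$sd
  expect_equal(f[1:30, 1:30, 1], want)

  st_pos <- dwt_standardizer(pyrs[1:3], scope = "position")
  expect_equal(dim(st_pos$stats$A$mean), c(30L, 30L))
  fp <- assemble_features(pyrs[[4]], "stacked10", stats = st_pos)
  want_pos <- (a3 - st_pos$stats$A$mean) / st_pos$stats$A$sd
  expect_equal(fp[1:30, 1:30, 1], want_pos)
  expect_error(dwt_standardizer(pyrs[1], scope = "position"),
               "at least two")
})

test_that("per-position centering removes the component shared by all images", {
  set.seed(92)
  common <- matrix(stats::runif(240^2, 50, 200), 240, 240)
  pyrs <- lapply(1:8, function(i) {
    haar_pyramid(common + matrix(stats::rnorm(240^2, 0, 2), 240, 240), 3L)
  })
  cosine <- function(f1, f2) sum(f1 * f2) / sqrt(sum(f1^2) * sum(f2^2))
  st <- dwt_standardizer(pyrs)
  f1 <- as.numeric(assemble_features(pyrs[[1]], "stacked10", stats = st))
  f2 <- as.numeric(assemble_features(pyrs[[2]], "stacked10", stats = st))
  expect_lt(abs(cosine(f1, f2)), 0.3)
  # versus near-total collinearity under scalar sub-band scaling
  st_band <- dwt_standardizer(pyrs, scope = "subband")
  g1 <- as.numeric(assemble_features(pyrs[[1]], "stacked10", stats = st_band))
  g2 <- as.numeric(assemble_features(pyrs[[2]], "stacked10", stats = st_band))
  expect_gt(cosine(g1, g2), 0.99)
})
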