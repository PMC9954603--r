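# Shared fixtures, all generated in code.

random_even_matrix <- function(n, m = n, integers = TRUE) {
  if (integers) {
    matrix(sample(0:255, n * m, replace = TRUE), n, m)
  } else {
    matrix(stats::runif(n * m, 0, 255), n, m)
  }
}

# Independent oracle for the single Haar step: direct per-pixel evaluation
# of the defining block sums/differences with explicit loops.
haar_step_loop_oracle <- function(img) {
  nr <- nrow(img) %/% 2L
  nc <- ncol(img) %/% 2L
  LL <- LH <- HL <- HH <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      p11 <- img[2 * i - 1, 2 * j - 1]
      p12 <- img[2 * i - 1, 2 * j]
      p21 <- img[2 * i, 2 * j - 1]
      p22 <- img[2 * i, 2 * j]
      LL[i, j] <- p11 + p12 + p21 + p22
      LH[i, j] <- -p11 - p12 + p21 + p22
      HL[i, j] <- -p11 + p12 - p21 + p22
      HH[i, j] <- p11 - p12 - p21 + p22
    }
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

# Single-level 2D Haar via PyWavelets, as an established external oracle.
# Returns NULL if python/pywt is unavailable.
pywt_haar_oracle <- function(img) {
  py <- Sys.which("python")
  if (py == "") return(NULL)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  in_csv <- file.path(dir, "in.csv")
  out_csv <- file.path(dir, "out.csv")
  utils::write.table(img, in_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "try:",
    "    import pywt",
    "except ImportError:",
    "    sys.exit(3)",
    sprintf("x = np.loadtxt(%s, delimiter=',')", shQuote(in_csv)),
    "cA, (cH, cV, cD) = pywt.dwt2(x, 'haar')",
    "np.savetxt(" ,
    sprintf("    %s,", shQuote(out_csv)),
    "    np.vstack([cA, cH, cV, cD]), delimiter=',')"
  ), script)
  status <- system2(py, script, stdout = FALSE, stderr = FALSE)
  if (status != 0L) return(NULL)
  m <- as.matrix(utils::read.table(out_csv, sep = ","))
  dimnames(m) <- NULL
  nr <- nrow(m) %/% 4L
  list(cA = m[seq_len(nr), , drop = FALSE],
       cH = m[nr + seq_len(nr), , drop = FALSE],
       cV = m[2L * nr + seq_len(nr), , drop = FALSE],
       cD = m[3L * nr + seq_len(nr), , drop = FALSE])
}

# Small balanced high-contrast phantom feature set for training tests.
make_training_set <- function(n_pos = 20L, n_neg = 20L,
                              layout = "compat1320x15", seed_base = 100L) {
  specs <- c(
    lapply(seq_len(n_pos), function(i) {
      phantom_spec(lesion_count = 1L, lesion_longest_axis = 60,
                   lesion_contrast = 2.0, seed = seed_base + i)
    }),
    lapply(seq_len(n_neg), function(i) {
      phantom_spec(lesion_count = 0L, seed = seed_base + 1000L + i)
    })
  )
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  pyr <- lapply(specs, function(s) haar_pyramid(generate_phantom(s)$pixels, 3L))
  stats <- dwt_standardizer(pyr)
  x <- lapply(pyr, assemble_features, layout = layout, stats = stats)
  list(x = x, y = y, pyramids = pyr, stats = stats)
}
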