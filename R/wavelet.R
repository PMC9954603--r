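#' Single-level 2D Haar wavelet analysis step
#'
#' Decomposes an even-sided grayscale image into the four Haar sub-bands by
#' 2x2 block sums and differences with stride 2. With
#' `normalization = "unnormalized"` (the default) the coefficients are the
#' plain block combinations
#' \deqn{LL(i,j) = y(2i-1,2j-1) + y(2i-1,2j) + y(2i,2j-1) + y(2i,2j)}
#' \deqn{LH(i,j) = -y(2i-1,2j-1) - y(2i-1,2j) + y(2i,2j-1) + y(2i,2j)}
#' \deqn{HL(i,j) = -y(2i-1,2j-1) + y(2i-1,2j) - y(2i,2j-1) + y(2i,2j)}
#' \deqn{HH(i,j) = y(2i-1,2j-1) - y(2i-1,2j) - y(2i,2j-1) + y(2i,2j)}
#' (1-based indexing; rows are the first index). `"orthonormal"` scales all
#' four sub-bands by 1/2, which makes the transform energy preserving.
#'
#' LH differences across rows and so responds to horizontal edges; HL to
#' vertical edges; HH to diagonal structure.
#'
#' @param image numeric matrix with both sides even.
#' @param normalization `"unnormalized"` or `"orthonormal"`.
#' @return An object of class `haar_subbands`: a list with matrices `LL`,
#'   `LH`, `HL`, `HH` (each half the input side) and the `normalization`
#'   used.
#' @seealso [inverse_haar_step()], [haar_pyramid()]
#' @examples
#' s <- haar_step(matrix(c(1, 3, 2, 4), 2, 2))
#' s$LL  # 10
#' @export
haar_step <- function(image, normalization = c("unnormalized", "orthonormal")) {
  normalization <- match.arg(normalization)
  image <- as_image_matrix(image)
  nr <- nrow(image)
  nc <- ncol(image)
  if (nr %% 2L != 0L || nc %% 2L != 0L) {
    stop("image sides must be even: pad or crop to even size", call. = FALSE)
  }
  odd_r <- seq.int(1L, nr, by = 2L)
  odd_c <- seq.int(1L, nc, by = 2L)
  a <- image[odd_r, odd_c, drop = FALSE]      # y(2i-1, 2j-1)
  b <- image[odd_r, odd_c + 1L, drop = FALSE] # y(2i-1, 2j)
  c_ <- image[odd_r + 1L, odd_c, drop = FALSE] # y(2i,   2j-1)
  d <- image[odd_r + 1L, odd_c + 1L, drop = FALSE]
  out <- list(
    LL = a + b + c_ + d,
    LH = -a - b + c_ + d,
    HL = -a + b - c_ + d,
    HH = a - b - c_ + d,
    normalization = normalization
  )
  if (normalization == "orthonormal") {
    out[c("LL", "LH", "HL", "HH")] <-
      lapply(out[c("LL", "LH", "HL", "HH")], function(m) m / 2)
  }
  structure(out, class = "haar_subbands")
}

#' Single-level 2D Haar synthesis (inverse) step
#'
#' Algebraic inverse of [haar_step()]. For unnormalized sub-bands the four
#' pixels of each 2x2 block are recovered as
#' `y(2i-1,2j-1) = (LL - LH - HL + HH)/4` and the three sign-flipped
#' companions; exact (no rounding) for integer-valued inputs.
#'
#' @param subbands a `haar_subbands` object, or a list with elements
#'   `LL`, `LH`, `HL`, `HH` of identical shape (then assumed unnormalized
#'   unless a `normalization` element says otherwise).
#' @return numeric matrix of twice the sub-band side.
#' @export
inverse_haar_step <- function(subbands) {
  need <- c("LL", "LH", "HL", "HH")
  if (!all(need %in% names(subbands))) {
    stop("subbands must contain LL, LH, HL and HH", call. = FALSE)
  }
  dims <- lapply(subbands[need], dim)
  if (length(unique(dims)) != 1L) {
    stop("sub-band shape mismatch", call. = FALSE)
  }
  sc <- if (identical(subbands$normalization, "orthonormal")) 2 else 4
  LL <- subbands$LL
  LH <- subbands$LH
  HL <- subbands$HL
  HH <- subbands$HH
  nr <- nrow(LL)
  nc <- ncol(LL)
  out <- matrix(0, 2L * nr, 2L * nc)
  odd_r <- seq.int(1L, 2L * nr, by = 2L)
  odd_c <- seq.int(1L, 2L * nc, by = 2L)
  out[odd_r, odd_c] <- (LL - LH - HL + HH) / sc
  out[odd_r, odd_c + 1L] <- (LL - LH + HL - HH) / sc
  out[odd_r + 1L, odd_c] <- (LL + LH - HL - HH) / sc
  out[odd_r + 1L, odd_c + 1L] <- (LL + LH + HL + HH) / sc
  out
}

#' Multilevel 2D Haar wavelet pyramid
#'
#' Recursively applies [haar_step()] to the approximation (LL) sub-band,
#' keeping the three detail sub-bands at every level plus the final
#' approximation. A `levels = 3` decomposition of a 240x240 slice yields 10
#' sub-bands: the 30x30 approximation `A3` and horizontal/vertical/diagonal
#' details at sides 120, 60 and 30.
#'
#' @param image numeric matrix whose side is divisible by `2^levels`.
#' @param levels integer >= 1, number of decomposition levels.
#' @inheritParams haar_step
#' @return An object of class `haar_pyramid`: list with `approximation`
#'   (matrix), `details` (list of per-level lists with `horizontal`,
#'   `vertical`, `diagonal` — level 1 is the finest), `levels`,
#'   `original_dim` and `normalization`.
#' @export
haar_pyramid <- function(image, levels = 3L,
                         normalization = c("unnormalized", "orthonormal")) {
  normalization <- match.arg(normalization)
  image <- as_image_matrix(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (nrow(image) %% (2L^levels) != 0L || ncol(image) %% (2L^levels) != 0L) {
    stop("image side must be divisible by 2^levels", call. = FALSE)
  }
  details <- vector("list", levels)
  approx <- image
  for (k in seq_len(levels)) {
    s <- haar_step(approx, normalization)
    details[[k]] <- list(horizontal = s$LH, vertical = s$HL, diagonal = s$HH)
    approx <- s$LL
  }
  structure(
    list(
      approximation = approx,
      details = details,
      levels = levels,
      original_dim = dim(image),
      normalization = normalization
    ),
    class = "haar_pyramid"
  )
}

#' Reconstruct an image from a Haar pyramid
#'
#' Repeatedly applies [inverse_haar_step()] from the coarsest level to the
#' finest. Round-trips [haar_pyramid()] exactly on integer-valued inputs.
#'
#' @param pyramid a `haar_pyramid` object.
#' @return numeric matrix with the original dimensions.
#' @export
haar_reconstruct <- function(pyramid) {
  stopifnot(inherits(pyramid, "haar_pyramid"))
  approx <- pyramid$approximation
  for (k in rev(seq_len(pyramid$levels))) {
    d <- pyramid$details[[k]]
    approx <- inverse_haar_step(list(
      LL = approx, LH = d$horizontal, HL = d$vertical, HH = d$diagonal,
      normalization = pyramid$normalization
    ))
  }
  approx
}

#' @export
print.haar_pyramid <- function(x, ...) {
  cat(sprintf(
    "Haar wavelet pyramid: %d level(s) of a %dx%d image (%s)\n",
    x$levels, x$original_dim[1], x$original_dim[2], x$normalization
  ))
  cat(sprintf("  approximation: %dx%d\n",
              nrow(x$approximation), ncol(x$approximation)))
  for (k in seq_len(x$levels)) {
    cat(sprintf("  level %d details: %dx%d (horizontal, vertical, diagonal)\n",
                k, nrow(x$details[[k]]$horizontal),
                ncol(x$details[[k]]$horizontal)))
  }
  invisible(x)
}

#' @export
print.haar_subbands <- function(x, ...) {
  cat(sprintf("Haar sub-bands (%s): LL/LH/HL/HH each %dx%d\n",
              x$normalization, nrow(x$LL), ncol(x$LL)))
  invisible(x)
}

#' Zero-pad a coefficient matrix to a target square side
#'
#' Padding is appended bottom/right so the coefficient origin stays fixed;
#' the original values are unchanged.
#'
#' @param coeffs numeric matrix with sides `<= side`.
#' @param side target side in pixels.
#' @return `side` x `side` matrix.
#' @export
pad_to <- function(coeffs, side) {
  coeffs <- as_image_matrix(coeffs)
  side <- as.integer(side)
  if (nrow(coeffs) > side || ncol(coeffs) > side) {
    stop("coefficient matrix larger than target side", call. = FALSE)
  }
  out <- matrix(0, side, side)
  out[seq_len(nrow(coeffs)), seq_len(ncol(coeffs))] <- coeffs
  out
}

# Sub-bands of a 3-level pyramid in stacking order: the coarse approximation
# first, then details from coarse to fine.
pyramid_subband_list <- function(pyramid) {
  stopifnot(inherits(pyramid, "haar_pyramid"))
  out <- list(A = pyramid$approximation)
  nm <- "A"
  for (k in rev(seq_len(pyramid$levels))) {
    d <- pyramid$details[[k]]
    out[[sprintf("D%dh", k)]] <- d$horizontal
    out[[sprintf("D%dv", k)]] <- d$vertical
    out[[sprintf("D%dd", k)]] <- d$diagonal
  }
  out
}

#' Standardization statistics for wavelet features from a training set
#'
#' Computes coefficient standardization statistics over a list of training
#' pyramids, to be passed to [assemble_features()] so that test-time
#' features reuse the training statistics. Two scopes are supported:
#'
#' \describe{
#'   \item{`"position"` (default)}{mean and standard deviation per
#'     coefficient position, across the training pyramids — the
#'     conventional feature-wise scaler. Centering per position removes
#'     the component shared by all images (in brain slices, the common
#'     anatomy), which decorrelates the feature tensors across images;
#'     without it the inputs of different slices are nearly collinear and
#'     gradient training stalls. Requires at least two pyramids.}
#'   \item{`"subband"`}{a single mean/sd per sub-band, pooled over all its
#'     coefficients and all training pyramids — a scalar re-scaling that
#'     preserves the common anatomy in the features.}
#' }
#'
#' @param pyramids list of `haar_pyramid` objects with identical structure.
#' @param scope `"position"` or `"subband"`.
#' @return object of class `dwt_standardizer`.
#' @export
dwt_standardizer <- function(pyramids, scope = c("position", "subband")) {
  scope <- match.arg(scope)
  stopifnot(length(pyramids) >= 1L)
  if (scope == "position" && length(pyramids) < 2L) {
    stop("per-position statistics need at least two training pyramids",
         call. = FALSE)
  }
  bands <- lapply(pyramids, pyramid_subband_list)
  nm <- names(bands[[1]])
  stats <- lapply(nm, function(b) {
    if (scope == "subband") {
      v <- unlist(lapply(bands, function(x) as.numeric(x[[b]])),
                  use.names = FALSE)
      list(mean = mean(v), sd = stats::sd(v))
    } else {
      m <- vapply(bands, function(x) x[[b]],
                  bands[[1]][[b]])  # (rows, cols, images)
      list(mean = apply(m, c(1L, 2L), mean),
           sd = apply(m, c(1L, 2L), stats::sd))
    }
  })
  names(stats) <- nm
  structure(list(stats = stats, subbands = nm, scope = scope),
            class = "dwt_standardizer")
}

#' @export
print.dwt_standardizer <- function(x, ...) {
  cat(sprintf("dwt_standardizer: %s-scope statistics for %d sub-bands (%s)\n",
              x$scope, length(x$subbands),
              paste(x$subbands, collapse = ", ")))
  invisible(x)
}

#' Assemble a CNN feature tensor from a 3-level Haar pyramid
#'
#' Each of the 10 sub-bands is zero-padded bottom/right to 120x120
#' ([pad_to()]) and standardized to zero mean, unit variance — by default
#' per sub-band within the image; when `stats` (a [dwt_standardizer()]) is
#' given, with the persisted training statistics. A zero-variance sub-band
#' maps to all zeros rather than NaN.
#'
#' Two layouts are supported:
#' \describe{
#'   \item{`stacked10`}{the 10 padded sub-bands concatenated vertically,
#'     shape (1200, 120, 1). Order: approximation `A3`, then details from
#'     coarse (level 3) to fine (level 1), horizontal/vertical/diagonal
#'     within each level.}
#'   \item{`compat1320x15`}{compatibility layout of shape (1320, 15, 1): the
#'     144,000 stacked values are raveled row-major, truncated to 19,800 and
#'     reshaped row-major. This is a declared reshaping convention, not a
#'     derivable consequence of the sub-band sizes; with the stacking order
#'     above it retains the entire level-3 approximation.}
#' }
#'
#' @param pyramid a 3-level `haar_pyramid` of a 240x240 image.
#' @param layout `"stacked10"` or `"compat1320x15"`.
#' @param stats optional `dwt_standardizer` with training statistics.
#' @return 3D array (height, width, 1) with attributes `layout` and
#'   `subband_order`.
#' @export
assemble_features <- function(pyramid,
                              layout = c("stacked10", "compat1320x15"),
                              stats = NULL) {
  layout <- match.arg(layout)
  stopifnot(inherits(pyramid, "haar_pyramid"))
  if (pyramid$levels != 3L) {
    stop("feature assembly requires a 3-level pyramid", call. = FALSE)
  }
  if (!all(pyramid$original_dim == c(240L, 240L))) {
    stop("feature assembly expects a 240x240 source image", call. = FALSE)
  }
  bands <- pyramid_subband_list(pyramid)
  side <- 120L
  z <- lapply(names(bands), function(b) {
    m <- bands[[b]]
    if (!is.null(stats) && identical(stats$scope, "position")) {
      st <- stats$stats[[b]]
      zs <- (m - st$mean) / ifelse(st$sd > 1e-12, st$sd, 1)
      zs[!is.finite(zs) | st$sd <= 1e-12] <- 0
    } else {
      if (!is.null(stats)) {
        st <- stats$stats[[b]]
        mu <- st$mean
        sdv <- st$sd
      } else {
        mu <- mean(m)
        sdv <- stats::sd(as.numeric(m))
      }
      zs <- if (!is.finite(sdv) || sdv == 0) {
        matrix(0, nrow(m), ncol(m))
      } else {
        (m - mu) / sdv
      }
    }
    pad_to(zs, side)
  })
  stacked <- do.call(rbind, z)  # (1200, 120)
  if (layout == "stacked10") {
    out <- array(stacked, dim = c(1200L, 120L, 1L))
  } else {
    flat <- as.numeric(t(stacked))  # row-major ravel
    keep <- 1320L * 15L
    flat <- flat[seq_len(keep)]
    out <- array(t(matrix(flat, nrow = 15L, ncol = 1320L)),
                 dim = c(1320L, 15L, 1L))
  }
  attr(out, "layout") <- layout
  attr(out, "subband_order") <- names(bands)
  out
}

# Coerce to a plain numeric matrix, accepting integer input.
as_image_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}
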