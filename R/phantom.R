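#' Specification of a synthetic axial T2-like brain slice
#'
#' Collects the parameters from which [generate_phantom()] renders one
#' labeled slice. The phantom emulates an axial T2-weighted appearance:
#' a centered elliptical "brain" of mid-gray tissue with a smoothed noise
#' texture, optional hyperintense lesions (fluid-rich pathology is bright on
#' T2) and an optional bright skull ring around the brain.
#'
#' @param image_side side of the square image in pixels; must be even
#'   (the halving wavelet transform requires it). Default 240.
#' @param has_skull render a bright closed skull ring around the brain.
#' @param lesion_count number of lesions (0 = negative slice).
#' @param lesion_longest_axis longest axis of each lesion in pixels, in
#'   \[2, 105\].
#' @param lesion_contrast multiplicative hyperintensity of the lesion
#'   relative to surrounding tissue; must be > 1. Default 1.8 (a clearly
#'   visible lesion); ambiguous low-contrast cases use values near 1.15.
#' @param tissue_noise_sd standard deviation (intensity units on the 0-255
#'   scale) of the Gaussian texture field before smoothing. Default 8.
#' @param seed integer seed; the rendered slice is a pure function of the
#'   spec including this seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_side = 240L, has_skull = FALSE,
                         lesion_count = 1L, lesion_longest_axis = 40,
                         lesion_contrast = 1.8, tissue_noise_sd = 8,
                         seed = 1L) {
  image_side <- as.integer(image_side)
  if (image_side <= 0L || image_side %% 2L != 0L) {
    stop("image_side must be a positive even number of pixels", call. = FALSE)
  }
  lesion_count <- as.integer(lesion_count)
  if (lesion_count < 0L) stop("lesion_count must be >= 0", call. = FALSE)
  if (lesion_count > 0L &&
      (lesion_longest_axis < 2 || lesion_longest_axis > 105)) {
    stop("lesion_longest_axis must be in [2, 105] pixels", call. = FALSE)
  }
  if (lesion_count > 0L && lesion_contrast <= 1) {
    stop("lesion_contrast must be > 1", call. = FALSE)
  }
  structure(
    list(
      image_side = image_side, has_skull = isTRUE(has_skull),
      lesion_count = lesion_count,
      lesion_longest_axis = lesion_longest_axis,
      lesion_contrast = lesion_contrast,
      tissue_noise_sd = tissue_noise_sd, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Filled-ellipse mask on an nr x nc pixel grid. Semi-axes are chosen so the
# longest pixel run equals `axis_px`: the extreme pixel centers are
# (axis_px - 1) apart.
ellipse_mask <- function(nr, nc, cx, cy, a, b, theta = 0) {
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  xr <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
  yr <- -(x - cx) * sin(theta) + (y - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# Smoothed Gaussian random field with approximately the requested sd after
# smoothing; gives the wavelet detail sub-bands non-trivial content.
smooth_noise_field <- function(nr, nc, sd) {
  if (sd <= 0) return(matrix(0, nr, nc))
  raw <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- stats::dnorm(-2:2, sd = 1)
  k <- k / sum(k)
  sm <- t(apply(apply(raw, 2, stats::filter, filter = k, sides = 2), 1,
                stats::filter, filter = k, sides = 2))
  sm[is.na(sm)] <- 0
  s <- stats::sd(as.numeric(sm))
  if (s > 0) sm <- sm / s
  sm * sd
}

#' Generate a synthetic labeled brain slice
#'
#' Renders the slice described by a [phantom_spec()]. Deterministic:
#' identical specs (including the seed) produce byte-identical pixel grids.
#' The label is positive exactly when `lesion_count > 0`.
#'
#' @param spec a `phantom_spec`.
#' @return object of class `labeled_slice`: list with `pixels` (matrix of
#'   doubles in \[0, 255\]), `label` (0/1), and `metadata` (the spec plus
#'   construction masks: `brain_mask`, `lesion_mask`, `skull_mask`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_side
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)

  cx <- n / 2 + 0.5
  cy <- n / 2 + 0.5
  # brain ellipse: taller than wide, filling most of the frame. The geometry
  # is fixed across phantoms — only texture and lesions vary; anatomical
  # shape variability is outside the phantom's scope.
  a <- 0.33 * n
  b <- 0.40 * n
  brain <- ellipse_mask(n, n, cx, cy, a, b)

  tissue_mean <- 100
  img <- matrix(0, n, n)
  img[brain] <- tissue_mean
  img <- img + smooth_noise_field(n, n, spec$tissue_noise_sd) * brain

  lesion_mask <- matrix(FALSE, n, n)
  if (spec$lesion_count > 0L) {
    for (i in seq_len(spec$lesion_count)) {
      L <- spec$lesion_longest_axis
      amax <- (L - 1) / 2
      bmin <- max(amax * stats::runif(1, 0.55, 0.9), 0.5)
      theta <- stats::runif(1, 0, pi)
      # place fully inside the brain ellipse (centre drawn in a shrunken copy)
      repeat {
        px <- cx + stats::runif(1, -1, 1) * (a - amax - 2)
        py <- cy + stats::runif(1, -1, 1) * (b - amax - 2)
        if (((px - cx) / (a - amax - 2))^2 +
            ((py - cy) / (b - amax - 2))^2 <= 1) break
      }
      # half-pixel coverage inflation so the rasterized tips always contain
      # a pixel centre regardless of orientation
      m <- ellipse_mask(n, n, px, py, max(amax, 0.5) + 0.5, bmin + 0.5, theta)
      lesion_mask <- lesion_mask | m
    }
    # multiplicative hyperintensity with a softened boundary
    soft <- blur_mask(lesion_mask * 1)
    img <- img * (1 + (spec$lesion_contrast - 1) * soft)
  }

  skull_mask <- matrix(FALSE, n, n)
  if (spec$has_skull) {
    gap <- 0.02 * n
    thick <- 0.018 * n
    outer <- ellipse_mask(n, n, cx, cy, a + gap + thick, b + gap + thick)
    inner <- ellipse_mask(n, n, cx, cy, a + gap, b + gap)
    skull_mask <- outer & !inner
    img[skull_mask] <- 220
  }

  img <- pmin(pmax(img, 0), 255)
  structure(
    list(
      pixels = img,
      label = as.integer(spec$lesion_count > 0L),
      metadata = list(
        spec = spec, augmentation = NULL,
        brain_mask = brain, lesion_mask = lesion_mask, skull_mask = skull_mask
      )
    ),
    class = "labeled_slice"
  )
}

# 3x3 box blur of a 0/1 mask, clipped to [0, 1]; softens lesion rims.
blur_mask <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      src_r <- pmin(pmax(seq_len(nr) + di, 1L), nr)
      src_c <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
      acc <- acc + m[src_r, src_c]
    }
  }
  pmin(acc / 9 * 1.5, 1)
}

#' @export
print.labeled_slice <- function(x, ...) {
  cat(sprintf(
    "labeled_slice: %dx%d, label = %d (%s)%s\n",
    nrow(x$pixels), ncol(x$pixels), x$label,
    if (x$label == 1L) "lesion present" else "no lesion",
    if (!is.null(x$metadata$augmentation)) " [augmented]" else ""
  ))
  invisible(x)
}

#' Longest axis of a binary mask, in pixels
#'
#' Measured as the maximum pairwise Euclidean distance between pixel centres
#' of the mask plus one (so a straight run of k pixels has axis k). Used to
#' verify lesion geometry.
#'
#' @param mask logical matrix.
#' @return numeric scalar (0 for an empty mask).
#' @export
mask_longest_axis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  # distances are maximized on the convex hull; boundary pixels suffice
  b <- idx[boundary_pixels(mask, idx), , drop = FALSE]
  if (nrow(b) == 1L) return(1)
  d <- stats::dist(b)
  max(d) + 1
}

boundary_pixels <- function(mask, idx) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  apply(idx, 1, function(p) {
    i <- p[1]
    j <- p[2]
    i == 1L || j == 1L || i == nr || j == nc ||
      !(mask[i - 1L, j] && mask[i + 1L, j] &&
          mask[i, j - 1L] && mask[i, j + 1L])
  })
}

#' Generate a dataset manifest of phantom slices
#'
#' Builds a manifest emulating the composition of a curated two-split T2
#' study: per-class slice counts for training and test, with the class
#' driving the phantom parameters. The default composition is the
#' `"study"` preset: 382 training slices (168 non-pathological, 151 other
#' disease, 34 glioma, 20 meningioma, 9 pituitary) and 190 test slices
#' (10 / 90 / 30 / 30 / 30).
#'
#' Class rendering: gliomas get large high-contrast lesions (10% of tumor
#' slices are rendered as ambiguous low-contrast cases), meningioma and
#' pituitary tumors medium lesions, other-disease slices small low-contrast
#' lesions, non-pathological slices none. Non-tumor classes carry a skull
#' ring (their source scans are not skull-stripped); tumor classes do not.
#'
#' @param composition `"study"` or a data.frame with columns `class`,
#'   `train`, `test` (classes among non_pathological, other_disease,
#'   glioma, meningioma, pituitary).
#' @param seed integer seed controlling every slice seed.
#' @param positive_class `"glioma"` (only glioma slices are positive) or
#'   `"any-tumor"` (glioma, meningioma and pituitary are positive). Which
#'   class is "positive" is a study-design choice, so it is exposed rather
#'   than fixed.
#' @param ambiguous_fraction fraction of tumor slices rendered with low
#'   lesion contrast. Default 0.1.
#' @return object of class `gw_manifest`: a data.frame with one row per
#'   slice (columns `id`, `class`, `label`, `split`, `seed`, `has_skull`,
#'   `lesion_count`, `lesion_axis`, `lesion_contrast`, `augmented`,
#'   `source_id`, `aug_flip`, `aug_angle`, `aug_dx`, `aug_dy`).
#' @export
generate_dataset <- function(composition = "study", seed = 1L,
                             positive_class = c("glioma", "any-tumor"),
                             ambiguous_fraction = 0.1) {
  positive_class <- match.arg(positive_class)
  if (identical(composition, "study")) {
    composition <- data.frame(
      class = c("non_pathological", "other_disease", "glioma",
                "meningioma", "pituitary"),
      train = c(168L, 151L, 34L, 20L, 9L),
      test = c(10L, 90L, 30L, 30L, 30L)
    )
  }
  stopifnot(is.data.frame(composition),
            all(c("class", "train", "test") %in% names(composition)),
            all(composition$train >= 0L), all(composition$test >= 0L))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  tumor_classes <- c("glioma", "meningioma", "pituitary")
  rows <- list()
  counter <- 0L
  for (r in seq_len(nrow(composition))) {
    cls <- composition$class[r]
    for (split in c("train", "test")) {
      k <- composition[[split]][r]
      if (k == 0L) next
      for (i in seq_len(k)) {
        counter <- counter + 1L
        is_tumor <- cls %in% tumor_classes
        ambiguous <- is_tumor && stats::runif(1) < ambiguous_fraction
        params <- switch(cls,
          non_pathological = list(n = 0L, axis = NA_real_, contrast = NA_real_),
          other_disease = list(
            n = sample(1:3, 1L),
            axis = stats::runif(1, 2, 15),
            contrast = stats::runif(1, 1.05, 1.25)
          ),
          glioma = list(
            n = 1L,
            axis = stats::runif(1, 20, 105),
            contrast = if (ambiguous) stats::runif(1, 1.08, 1.2)
                       else stats::runif(1, 1.5, 2.2)
          ),
          list( # meningioma / pituitary
            n = 1L,
            axis = stats::runif(1, 8, 40),
            contrast = if (ambiguous) stats::runif(1, 1.08, 1.2)
                       else stats::runif(1, 1.3, 1.8)
          )
        )
        label <- if (positive_class == "glioma") {
          as.integer(cls == "glioma")
        } else {
          as.integer(is_tumor)
        }
        rows[[counter]] <- data.frame(
          id = sprintf("slice_%05d", counter), class = cls, label = label,
          split = split,
          seed = sample.int(.Machine$integer.max, 1L),
          has_skull = !is_tumor,
          lesion_count = params$n,
          lesion_axis = params$axis,
          lesion_contrast = params$contrast,
          augmented = FALSE, source_id = NA_character_,
          aug_flip = FALSE, aug_angle = 0, aug_dx = 0L, aug_dy = 0L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  man <- if (length(rows)) do.call(rbind, rows) else
    data.frame(
      id = character(), class = character(), label = integer(),
      split = character(), seed = integer(), has_skull = logical(),
      lesion_count = integer(), lesion_axis = numeric(),
      lesion_contrast = numeric(), augmented = logical(),
      source_id = character(), aug_flip = logical(), aug_angle = numeric(),
      aug_dx = integer(), aug_dy = integer(), stringsAsFactors = FALSE
    )
  attr(man, "positive_class") <- positive_class
  class(man) <- c("gw_manifest", "data.frame")
  man
}

#' @export
print.gw_manifest <- function(x, ...) {
  cat(sprintf("Phantom dataset manifest: %d slice(s)\n", nrow(x)))
  if (nrow(x)) {
    print(table(split = x$split, class = x$class))
    cat(sprintf("positive class: %s; positives: %d\n",
                attr(x, "positive_class"), sum(x$label)))
  }
  invisible(x)
}

#' Double a manifest by label-preserving augmentation
#'
#' Pairs every entry with one transformed copy drawn from a seeded set of
#' label-preserving transforms: horizontal flip, rotation up to +/-10
#' degrees, translation up to +/-5 pixels. The transform parameters are
#' recorded in the manifest; [manifest_slice()] applies them when the
#' augmented slice is materialized.
#'
#' @param manifest a `gw_manifest`.
#' @param seed integer seed for the transform draws.
#' @param max_angle,max_shift bounds of the rotation (degrees) and
#'   translation (pixels) draws.
#' @return a `gw_manifest` with exactly `2 * nrow(manifest)` entries.
#' @export
augment_x2 <- function(manifest, seed = 1L, max_angle = 10, max_shift = 5L) {
  stopifnot(inherits(manifest, "gw_manifest"))
  if (nrow(manifest) == 0L) return(manifest)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  aug <- manifest
  aug$id <- paste0(manifest$id, "_aug")
  aug$augmented <- TRUE
  aug$source_id <- manifest$id
  n <- nrow(manifest)
  aug$aug_flip <- stats::runif(n) < 0.5
  aug$aug_angle <- stats::runif(n, -max_angle, max_angle)
  aug$aug_dx <- as.integer(round(stats::runif(n, -max_shift, max_shift)))
  aug$aug_dy <- as.integer(round(stats::runif(n, -max_shift, max_shift)))
  out <- rbind(as.data.frame(manifest), as.data.frame(aug))
  attr(out, "positive_class") <- attr(manifest, "positive_class")
  class(out) <- c("gw_manifest", "data.frame")
  out
}

#' Materialize one manifest row as a labeled slice
#'
#' Renders the phantom for a manifest row, applying the recorded
#' augmentation transform if the row is an augmented copy.
#'
#' @param manifest a `gw_manifest`.
#' @param i row index.
#' @param image_side image side passed to [phantom_spec()].
#' @return a `labeled_slice`.
#' @export
manifest_slice <- function(manifest, i, image_side = 240L) {
  stopifnot(inherits(manifest, "gw_manifest"), i >= 1L, i <= nrow(manifest))
  row <- manifest[i, ]
  spec <- phantom_spec(
    image_side = image_side, has_skull = row$has_skull,
    lesion_count = row$lesion_count,
    lesion_longest_axis = if (row$lesion_count > 0L) row$lesion_axis else 40,
    lesion_contrast = if (row$lesion_count > 0L) row$lesion_contrast else 1.8,
    seed = row$seed
  )
  slice <- generate_phantom(spec)
  slice$label <- row$label  # manifest label (depends on positive_class)
  if (isTRUE(row$augmented)) {
    px <- slice$pixels
    if (row$aug_flip) px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
    if (row$aug_angle != 0) {
      px <- ebimage_rotate(px, row$aug_angle)
    }
    if (row$aug_dx != 0L || row$aug_dy != 0L) {
      px <- shift_image(px, row$aug_dy, row$aug_dx)
    }
    slice$pixels <- pmin(pmax(px, 0), 255)
    slice$metadata$augmentation <- list(
      flip = row$aug_flip, angle = row$aug_angle,
      dx = row$aug_dx, dy = row$aug_dy
    )
  }
  slice
}

# Rotate about the centre, keeping the original frame, zero background.
ebimage_rotate <- function(px, angle) {
  img <- EBImage::Image(px / 255)
  out <- EBImage::rotate(img, angle, output.dim = dim(px), bg.col = 0)
  EBImage::imageData(out) * 255
}

shift_image <- function(px, dr, dc) {
  nr <- nrow(px)
  nc <- ncol(px)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- px[src_r[ok_r], src_c[ok_c]]
  out
}

# Run code under a private RNG stream, restoring the caller's state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
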