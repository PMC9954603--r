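#' Skull stripping of an axial slice
#'
#' Removes the bright skull ring and background from a 2D slice by a
#' classical threshold/edge/morphology chain: global Otsu threshold,
#' morphological erosion to detach the thin skull ring from the brain,
#' largest 4-connected component, dilation back, and hole filling. Pixels
#' outside the resulting brain mask are set to zero.
#'
#' @param slice a `labeled_slice` or a numeric matrix of intensities in
#'   \[0, 255\].
#' @param erode_radius,dilate_radius radii (pixels) of the disc structuring
#'   elements. Defaults 3 / 3; erosion must exceed half the skull thickness
#'   to detach the ring.
#' @return list with `slice` (same type as the input, masked pixels zeroed)
#'   and `mask` (object of class `brain_mask`: logical matrix plus a record
#'   of the steps applied).
#' @export
skull_strip <- function(slice, erode_radius = 3L, dilate_radius = 3L) {
  px <- slice_pixels(slice)
  if (all(px == 0)) stop("empty image", call. = FALSE)
  img <- EBImage::Image(t(px) / 255)  # EBImage is (x, y)
  thr <- EBImage::otsu(img)
  fg <- img > thr
  brush_e <- EBImage::makeBrush(2L * erode_radius + 1L, shape = "disc")
  brush_d <- EBImage::makeBrush(2L * dilate_radius + 1L, shape = "disc")
  er <- EBImage::erode(fg, brush_e)
  lab <- EBImage::bwlabel(er)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0L || all(tab == 0L)) {
    # erosion removed everything; fall back to the raw foreground
    core <- fg
  } else {
    keep <- which.max(tab)
    core <- EBImage::Image(EBImage::imageData(lab) == keep)
  }
  di <- EBImage::dilate(core, brush_d)
  filled <- EBImage::fillHull(di)
  mask <- t(EBImage::imageData(filled)) > 0  # back to (row, col)
  out_px <- px * mask
  out <- set_slice_pixels(slice, out_px)
  structure_mask <- structure(
    list(
      mask = mask,
      method = list(
        steps = c("otsu", "erode", "largest_component", "dilate", "fill_hull"),
        otsu_threshold = as.numeric(thr) * 255,
        erode_radius = erode_radius, dilate_radius = dilate_radius
      )
    ),
    class = "brain_mask"
  )
  list(slice = out, mask = structure_mask)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: %dx%d, %d pixels in mask (steps: %s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              paste(x$method$steps, collapse = " > ")))
  invisible(x)
}

#' Rescale intensities from \[0, 255\] to \[0, 1\]
#'
#' The affine map `v / 255`; order preserving and invertible up to
#' quantization of the source.
#'
#' @param slice a `labeled_slice` or numeric matrix with values in
#'   \[0, 255\].
#' @return same type as the input with pixel values in \[0, 1\].
#' @export
normalize_intensities <- function(slice) {
  px <- slice_pixels(slice)
  if (any(px < 0 | px > 255)) {
    stop("pixel values outside [0, 255]", call. = FALSE)
  }
  set_slice_pixels(slice, px / 255)
}

#' Resample a slice to a square target side
#'
#' Non-square inputs are first centre-cropped/padded to a square, then
#' bilinearly resampled to `side` x `side` (nearest neighbour available for
#' label masks).
#'
#' @param slice a `labeled_slice` or numeric matrix.
#' @param side even target side in pixels.
#' @param method `"bilinear"` or `"nearest"`.
#' @return same type as the input, `side` x `side`.
#' @export
resize_to <- function(slice, side, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  side <- as.integer(side)
  if (side <= 0L) stop("side must be positive", call. = FALSE)
  px <- slice_pixels(slice)
  nr <- nrow(px)
  nc <- ncol(px)
  if (nr != nc) {
    s <- max(nr, nc)
    sq <- matrix(0, s, s)
    r0 <- (s - nr) %/% 2L
    c0 <- (s - nc) %/% 2L
    sq[r0 + seq_len(nr), c0 + seq_len(nc)] <- px
    px <- sq
  }
  if (nrow(px) == side) {
    return(set_slice_pixels(slice, px))
  }
  img <- EBImage::Image(t(px))
  out <- EBImage::resize(img, w = side, h = side,
                         filter = if (method == "bilinear") "bilinear"
                                  else "none")
  set_slice_pixels(slice, t(EBImage::imageData(out)))
}

slice_pixels <- function(slice) {
  if (inherits(slice, "labeled_slice")) slice$pixels else as_image_matrix(slice)
}

set_slice_pixels <- function(slice, px) {
  if (inherits(slice, "labeled_slice")) {
    slice$pixels <- px
    slice
  } else {
    px
  }
}

#' Prevalence of the positive class
#'
#' Proportion of condition-positive cases among all cases.
#'
#' @param labels vector of 0/1 (or logical) labels.
#' @return proportion in \[0, 1\].
#' @export
prevalence <- function(labels) {
  if (length(labels) == 0L) stop("empty label vector", call. = FALSE)
  mean(as.integer(as.logical(labels)))
}
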