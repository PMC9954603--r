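#' Read a 2D grayscale slice from disk
#'
#' Supported formats: 8-bit grayscale PNG (`.png`), a lossless
#' tab-separated array file (`.tsv`, doubles, exact round-trip), or a NIfTI
#' volume (`.nii` / `.nii.gz`, requires the RNifti package) with
#' `slice_index` selecting the axial slice. PNG values are rescaled to
#' 0-255; the 8-bit quantization of PNG is lossy for non-integer
#' intensities, which is why the array file is the canonical on-disk form.
#'
#' @param path input file.
#' @param slice_index axial slice index for NIfTI volumes.
#' @return numeric matrix of intensities in \[0, 255\].
#' @export
read_slice <- function(path, slice_index = 1L) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- paste0(ext, ".gz")
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img * 255
  } else if (ext == "tsv") {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    m
  } else if (ext %in% c("nii", "nii.gz")) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the RNifti package", call. = FALSE)
    }
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) < 3L) return(as.matrix(vol[, ]))
    if (slice_index < 1L || slice_index > d[3]) {
      stop("slice_index outside volume", call. = FALSE)
    }
    as.matrix(vol[, , slice_index])
  } else {
    stop(sprintf(
      "unsupported format '%s' (supported: png, tsv, nii, nii.gz)", ext
    ), call. = FALSE)
  }
}

#' Write a 2D grayscale slice to disk
#'
#' `.png` writes 8-bit grayscale (values clipped to 0-255 and quantized);
#' `.tsv` writes the full-precision array (lossless round-trip with
#' [read_slice()]).
#'
#' @param slice a `labeled_slice` or numeric matrix in \[0, 255\].
#' @param path output file, extension selects the format.
#' @export
write_slice <- function(slice, path) {
  px <- slice_pixels(slice)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(px, 0), 255) / 255, path)
  } else if (ext == "tsv") {
    # %.17g preserves doubles exactly through the text round-trip
    txt <- matrix(sprintf("%.17g", px), nrow(px), ncol(px))
    utils::write.table(txt, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    stop(sprintf("unsupported format '%s' (supported: png, tsv)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Write / read a dataset manifest as CSV
#'
#' @param manifest a `gw_manifest`.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "gw_manifest"))
  df <- as.data.frame(manifest)
  df$positive_class <- attr(manifest, "positive_class")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pc <- if ("positive_class" %in% names(df)) df$positive_class[1] else "glioma"
  df$positive_class <- NULL
  df$source_id <- as.character(df$source_id)
  attr(df, "positive_class") <- pc
  class(df) <- c("gw_manifest", "data.frame")
  df
}
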