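# Image helpers. Throughout the package images are plain numeric arrays on
# the 0..255 intensity scale: H x W matrices (grayscale) or H x W x 3 arrays
# (RGB). Conversion to [0,1] happens only at file boundaries.

#' Read an image file into a 0..255 numeric array
#'
#' Supports PNG (8/16-bit, via \pkg{png}) and TIFF (including 32-bit float
#' coefficient images, via \pkg{tiff} when available). Alpha channels are
#' dropped.
#'
#' @param path File path; format chosen by extension.
#' @return Numeric matrix (grayscale) or H x W x 3 array, 0..255 scale for
#'   PNG; float TIFFs are returned as stored.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path) * 255
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read ", path)
    x <- tiff::readTIFF(path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1L]
  x
}

#' Write a 0..255 numeric array as an 8-bit PNG
#'
#' Values are clipped to `[0, 255]`; quantisation rounds half-up, so writing
#' an array whose values are already exact multiples of 1 round-trips
#' bit-for-bit.
#'
#' @param image Numeric matrix or H x W x 3 array, 0..255 scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  x <- pmin(pmax(image / 255, 0), 1)
  png::writePNG(x, path)
  invisible(path)
}

#' Write a numeric array as a 32-bit float TIFF
#'
#' Used to persist raw (possibly negative) deconvolution coefficient planes
#' without quantisation.
#'
#' @param image Numeric matrix or array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write float TIFFs")
  tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

# promote grayscale to RGB; pass RGB through
to_rgb <- function(image) {
  if (length(dim(image)) == 3L) return(image)
  array(rep(image, 3L), dim = c(dim(image), 3L))
}
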