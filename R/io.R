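# Image and mask readers/writers shared by all modules. Images are H x W x 3
# float arrays in [0, 1] (RGB); binary masks are 0/255 8-bit PNG, binarized
# at > 127 on read; soft pseudo-labels round-trip through 16-bit TIFF.

#' Read an RGB image
#'
#' @param path path to a PNG file.
#' @return an `H x W x 3` array in `[0, 1]`; grayscale images are replicated
#'   across channels and an alpha channel, if present, is dropped.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3L] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3L] == 1L) {
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  }
  img
}

#' Write an RGB image as PNG
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp01(img), path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask binary `h x w` matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask, "mask")
  png::writePNG(mask * 1.0, path)
}

#' Read a binary mask from PNG
#'
#' @param path path to a PNG mask.
#' @param threshold gray level in `[0, 255]`; pixels strictly above it are
#'   foreground.
#' @return binary `h x w` matrix.
#' @export
read_mask <- function(path, threshold = 127) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > threshold / 255) * 1
}

#' Write a soft pseudo-label as 16-bit grayscale TIFF
#'
#' Values in `[0, 1]` are quantized to 16 bits, bounding the round-trip
#' error by `1/65535`.
#'
#' @param label `h x w` matrix in `[0, 1]`.
#' @param path output path (`.tif`).
#' @export
write_soft_label <- function(label, path) {
  tiff::writeTIFF(clamp01(label), path, bits.per.sample = 16L)
}

#' Read a soft pseudo-label written by [write_soft_label()]
#'
#' @param path path to a 16-bit TIFF.
#' @return `h x w` matrix in `[0, 1]`.
#' @export
read_soft_label <- function(path) {
  if (!file.exists(path)) stop("soft label file not found: ", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}
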