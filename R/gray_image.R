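#' Grayscale image container
#'
#' A light wrapper around a numeric matrix holding a single-channel
#' intensity raster together with its bit depth and an optional physical
#' pixel size. Rows index the y (vertical) axis, columns the x (horizontal)
#' axis, matching the layout returned by [tiff::readTIFF()].
#'
#' @param data numeric matrix of intensities in `[0, 2^depth - 1]`.
#' @param depth bit depth, 8 or 16.
#' @param pixel_size optional physical pixel size in nm/px (`NA` = unknown;
#'   all measurements are then reported in pixel units).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(data, depth = 8L, pixel_size = NA_real_) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix")
  if (!depth %in% c(8L, 16L)) stop("bit depth must be 8 or 16")
  maxv <- 2^depth - 1
  if (anyNA(data)) stop("image contains NA intensities")
  if (min(data) < 0 || max(data) > maxv)
    stop("intensities outside [0, 2^depth - 1]")
  structure(
    list(data = data, depth = as.integer(depth), pixel_size = pixel_size),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d px, %d-bit, range [%.1f, %.1f]%s\n",
    nrow(x$data), ncol(x$data), x$depth, min(x$data), max(x$data),
    if (is.na(x$pixel_size)) "" else sprintf(", %.3g nm/px", x$pixel_size)
  ))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$data)

is_gray_image <- function(x) inherits(x, "gray_image")

#' Maximum representable intensity of an image
#' @param img a [gray_image()].
#' @return `2^depth - 1`.
#' @export
gray_max <- function(img) 2^img$depth - 1

#' Invert image intensities
#'
#' Maps every pixel `v` to `(2^depth - 1) - v`. TEM mitochondria are
#' electron-dense and appear dark on a bright background; inversion makes
#' them bright so that downstream background subtraction and thresholding
#' operate with a bright-foreground convention.
#'
#' @param img a [gray_image()].
#' @return The inverted [gray_image()]; applying it twice restores the input.
#' @export
invert <- function(img) {
  stopifnot(is_gray_image(img))
  gray_image(gray_max(img) - img$data, img$depth, img$pixel_size)
}

#' Binarize an image at a threshold
#'
#' @param img a [gray_image()].
#' @param threshold gray level; pixels strictly above it become foreground.
#' @return A logical matrix (`TRUE` = foreground) with the image's shape.
#' @export
binarize <- function(img, threshold) {
  stopifnot(is_gray_image(img), is.numeric(threshold), length(threshold) == 1)
  if (threshold < 0 || threshold > gray_max(img))
    stop("threshold outside the gray range")
  img$data > threshold
}

#' Read a single-page grayscale TIFF
#'
#' @param path file path.
#' @param pixel_size optional nm/px to attach.
#' @return A [gray_image()]; 8- or 16-bit depending on the file.
#' @export
read_tiff_gray <- function(path, pixel_size = NA_real_) {
  raw <- tiff::readTIFF(path, as.is = TRUE, all = FALSE, info = TRUE)
  if (is.list(raw)) raw <- raw[[1]]
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] > 1) stop("multi-channel TIFF; a grayscale image is required")
    raw <- raw[, , 1]
  }
  bps <- attr(raw, "bits.per.sample")
  depth <- if (is.numeric(bps) && length(bps) == 1 && bps == 16) 16L
           else if (max(raw) > 255) 16L else 8L
  gray_image(matrix(as.numeric(raw), nrow(raw), ncol(raw)), depth, pixel_size)
}

#' Write a grayscale image as an uncompressed single-page TIFF
#'
#' Intensities are rounded to integers before writing, so a written image
#' re-read with [read_tiff_gray()] reproduces `round(img$data)` exactly.
#'
#' @param img a [gray_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(img, path) {
  stopifnot(is_gray_image(img))
  maxv <- gray_max(img)
  tiff::writeTIFF(round(img$data) / maxv, path,
                  bits.per.sample = img$depth, compression = "none")
  invisible(path)
}

#' Write a binary mask as a 0/255 TIFF
#' @param mask logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}
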