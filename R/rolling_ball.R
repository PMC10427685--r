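#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of an image as the grayscale
#' morphological opening with a ball-shaped (hemispherical) structuring
#' element of the given radius, then subtracts it. The ball's height is
#' measured in gray levels with a slope of one gray level per pixel of
#' radius. Because the opening never exceeds the image, the background
#' estimate satisfies `B <= img` everywhere and a constant image maps to an
#' all-zero output. Features whose spatial extent is well below the radius
#' are preserved; slowly varying illumination (the typical TEM gradient) is
#' removed. The subtracted image is rounded to the integer gray scale
#' (the chain processes integer-valued images at every stage).
#'
#' @param img a [gray_image()] (bright-background convention, i.e. after
#'   [invert()] for TEM input).
#' @param radius ball radius in pixels (default 60).
#' @param return_background also return the background estimate.
#' @return The background-subtracted [gray_image()] (clipped at 0). With
#'   `return_background = TRUE`, a list with elements `image` and
#'   `background`.
#' @export
rolling_ball_subtract <- function(img, radius = 60, return_background = FALSE) {
  stopifnot(is_gray_image(img))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("'radius' must be a single positive number")
  if (radius > min(dim(img$data)))
    stop("rolling-ball radius exceeds the image size")
  bg <- .cpp_ball_dilate(.cpp_ball_erode(img$data, radius), radius)
  out <- pmin(pmax(round(img$data - bg), 0), gray_max(img))
  res <- gray_image(out, img$depth, img$pixel_size)
  if (return_background) {
    list(image = res, background = bg)
  } else {
    res
  }
}
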