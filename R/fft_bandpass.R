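#' Bandpass transfer function gain
#'
#' Closed-form gain of the bandpass filter used by [fft_bandpass()], as a
#' function of spatial frequency (cycles/px) or, equivalently, structure
#' period (px/cycle). The filter is the product of
#' * a low-pass Gaussian `LP(f) = exp(-ln 2 * (f / f_small)^2)` with half
#'   gain at the small cutoff size, and
#' * a soft high-pass `HP(f) = 1 - c * exp(-k * (f / f_large)^2)` with half
#'   gain at the large cutoff size and a floor of `1 - c` at zero frequency
#'   (`c = 0.6`, `k = ln(c / 0.5)`), so that extended structures are
#'   attenuated below 50% but not annihilated, which keeps the interiors of
#'   large particles segmentable.
#'
#' Gains are therefore >= 50% strictly inside the (small, large) size band,
#' exactly 50% at each nominal cut, and monotonically lower outside.
#'
#' @param period structure size in px/cycle (used if `freq` is missing).
#' @param freq spatial frequency in cycles/px.
#' @param large large structure cutoff in px (default 60).
#' @param small small structure cutoff in px (default 8).
#' @return Gain in `[0, 1]`.
#' @export
bandpass_gain <- function(period = NULL, freq = NULL, large = 60, small = 8) {
  if (is.null(freq)) {
    stopifnot(!is.null(period))
    freq <- 1 / period
  }
  stopifnot(small > 0, large > small)
  f_l <- 1 / large
  f_s <- 1 / small
  cc <- 0.6
  k <- log(cc / 0.5)
  hp <- 1 - cc * exp(-k * (freq / f_l)^2)
  lp <- exp(-log(2) * (freq / f_s)^2)
  hp * lp
}

next_pow2 <- function(n) 2^ceiling(log2(n))

mirror_index <- function(n, p) {
  # indices extending 1:n to length p by edge-inclusive reflection
  if (p == n) return(seq_len(n))
  c(seq_len(n), seq(n, by = -1, length.out = p - n))
}

#' FFT bandpass filter with directional stripe suppression
#'
#' Filters structures by characteristic size: sizes within `(small, large)`
#' px are passed (gain >= 50%), larger and smaller structures are
#' attenuated (gain <= 50% at the nominal cuts, monotonically more
#' outside); see [bandpass_gain()] for the documented transfer function.
#' Scan-line stripes are removed by zeroing all frequency components whose
#' direction lies within `tolerance_pct`% of 90 degrees of the stripe
#' energy axis (for vertical stripes, intensity varies along x, so the
#' energy lies on the horizontal frequency axis), excluding the DC
#' component.
#'
#' The image is mirror-padded to the next power of two before the
#' transform and cropped afterwards. Output rescaling rule: the filter is
#' applied to the zero-mean image, the original mean is added back, and
#' the result is rounded to the integer gray scale and clipped to the
#' input dynamic range (the chain processes integer-valued images at
#' every stage).
#'
#' @param img a [gray_image()], at least 64 x 64 px.
#' @param large large structure cutoff in px (default 60).
#' @param small small structure cutoff in px (default 8).
#' @param stripe_direction `"vertical"`, `"horizontal"` or `"none"`.
#' @param tolerance_pct angular tolerance as a percentage of 90 degrees
#'   (default 5).
#' @return The filtered [gray_image()].
#' @export
fft_bandpass <- function(img, large = 60, small = 8,
                         stripe_direction = c("vertical", "horizontal", "none"),
                         tolerance_pct = 5) {
  stopifnot(is_gray_image(img))
  stripe_direction <- match.arg(stripe_direction)
  if (!is.numeric(large) || !is.numeric(small) || small <= 0 || large <= 0)
    stop("bandpass bounds must be positive")
  if (small >= large) stop("'small' must be below 'large'")
  if (stripe_direction != "none" &&
      (tolerance_pct <= 0 || tolerance_pct >= 100))
    stop("'tolerance_pct' must be in (0, 100)")
  nr <- nrow(img$data); nc <- ncol(img$data)
  if (min(nr, nc) < 64) stop("image must be at least 64 x 64 for FFT stages")

  pr <- next_pow2(nr); pc <- next_pow2(nc)
  mu <- mean(img$data)
  work <- (img$data - mu)[mirror_index(nr, pr), mirror_index(nc, pc)]

  # frequency grids in cycles/px (fy varies along rows, fx along columns)
  fy <- c(seq(0, floor(pr / 2)), seq(-(ceiling(pr / 2) - 1), -1)) / pr
  fx <- c(seq(0, floor(pc / 2)), seq(-(ceiling(pc / 2) - 1), -1)) / pc
  FY <- matrix(fy, pr, pc)
  FX <- matrix(fx, pr, pc, byrow = TRUE)
  fr <- sqrt(FX^2 + FY^2)
  gain <- bandpass_gain(freq = fr, large = large, small = small)
  gain[1, 1] <- 0 # DC handled by the mean re-add

  if (stripe_direction != "none") {
    tol_rad <- (tolerance_pct / 100) * (pi / 2)
    # angle of each frequency vector from the stripe energy axis
    ang <- if (stripe_direction == "vertical") {
      atan2(abs(FY), abs(FX)) # vertical stripes: energy on the fx axis
    } else {
      atan2(abs(FX), abs(FY))
    }
    kill <- ang <= tol_rad
    kill[1, 1] <- FALSE
    gain[kill] <- 0
  }

  filt <- Re(stats::fft(stats::fft(work) * gain, inverse = TRUE)) / (pr * pc)
  out <- round(filt[seq_len(nr), seq_len(nc)] + mu)
  out <- pmin(pmax(out, 0), gray_max(img))
  gray_image(out, img$depth, img$pixel_size)
}
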