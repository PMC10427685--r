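#' Maximum-entropy (Kapur) threshold
#'
#' Selects the gray level that maximizes the summed Shannon entropies of
#' the background class (levels `<= t`) and the foreground class (levels
#' `> t`) computed from the normalized histogram. Zero-probability bins
#' contribute nothing; thresholds that would leave either class empty are
#' not eligible. Ties are broken toward the lowest threshold.
#'
#' The histogram always uses 256 bins: 8-bit images are binned at integer
#' gray levels; 16-bit images are first binned into 256 equal-width levels
#' and the returned threshold is the upper gray value of the selected
#' background bin, so [binarize()] at the returned value reproduces the
#' binned classification.
#'
#' @param img a [gray_image()] with at least 2 distinct gray levels.
#' @return The threshold gray level (numeric scalar).
#' @export
max_entropy_threshold <- function(img) {
  stopifnot(is_gray_image(img))
  step <- 2^(img$depth - 8L)
  bins <- pmin(pmax(floor(img$data / step), 0), 255)
  counts <- tabulate(as.integer(bins) + 1L, nbins = 256L)
  t_bin <- max_entropy_from_counts(counts)
  (t_bin + 1) * step - 1
}

#' Maximum-entropy threshold from a histogram
#'
#' Core of [max_entropy_threshold()], operating directly on bin counts.
#' Exposed so that the entropy objective can be exercised on arbitrary
#' histograms.
#'
#' @param counts non-negative integer vector of histogram counts.
#' @return The 0-based index of the last background bin.
#' @export
max_entropy_from_counts <- function(counts) {
  if (any(counts < 0) || sum(counts) == 0) stop("invalid histogram")
  if (sum(counts > 0) < 2)
    stop("image is constant: no threshold exists")
  p <- counts / sum(counts)
  n <- length(p)
  cum <- cumsum(p)
  # cumulative sums of p*log(p), with 0 log 0 = 0
  plogp <- ifelse(p > 0, p * log(p), 0)
  cumplogp <- cumsum(plogp)
  total_plogp <- cumplogp[n]
  best_t <- NA_integer_
  best_h <- -Inf
  for (t in seq_len(n - 1)) { # background = bins 1..t (0-based t-1)
    pt <- cum[t]
    if (pt <= 0 || pt >= 1) next
    hb <- log(pt) - cumplogp[t] / pt
    hf <- log(1 - pt) - (total_plogp - cumplogp[t]) / (1 - pt)
    h <- hb + hf
    if (h > best_h + 1e-12) { # strict improvement: ties go to the lowest t
      best_h <- h
      best_t <- t - 1L
    }
  }
  if (is.na(best_t)) stop("no admissible threshold found")
  best_t
}
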