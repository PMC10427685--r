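#' Preprocessing/segmentation configuration
#'
#' Bundles every tunable of the segmentation chain. Defaults follow the
#' published TEM macro settings: rolling-ball radius 60 px, bandpass bounds
#' 60 and 8 px, vertical stripe suppression with 5% tolerance of direction,
#' maximum-entropy thresholding, and a strict 600 px particle size filter.
#'
#' @param rolling_ball_radius rolling-ball radius in px.
#' @param bandpass_large large structure cutoff in px.
#' @param bandpass_small small structure cutoff in px.
#' @param stripe_direction `"vertical"`, `"horizontal"` or `"none"`.
#' @param stripe_tolerance angular tolerance, % of 90 degrees, in (0, 100).
#' @param threshold_method only `"max_entropy"` is implemented.
#' @param min_particle_px particles must exceed this pixel count (strict).
#' @param fill_holes fill holes in particles before measuring (default off).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rolling_ball_radius = 60,
                            bandpass_large = 60,
                            bandpass_small = 8,
                            stripe_direction = c("vertical", "horizontal", "none"),
                            stripe_tolerance = 5,
                            threshold_method = "max_entropy",
                            min_particle_px = 600,
                            fill_holes = FALSE) {
  stripe_direction <- match.arg(stripe_direction)
  threshold_method <- match.arg(threshold_method, "max_entropy")
  if (rolling_ball_radius <= 0) stop("'rolling_ball_radius' must be > 0")
  if (bandpass_small <= 0 || bandpass_small >= bandpass_large)
    stop("need 0 < bandpass_small < bandpass_large")
  if (stripe_tolerance <= 0 || stripe_tolerance >= 100)
    stop("'stripe_tolerance' must be in (0, 100)")
  if (min_particle_px < 0) stop("'min_particle_px' must be >= 0")
  structure(list(
    rolling_ball_radius = rolling_ball_radius,
    bandpass_large = bandpass_large,
    bandpass_small = bandpass_small,
    stripe_direction = stripe_direction,
    stripe_tolerance = stripe_tolerance,
    threshold_method = threshold_method,
    min_particle_px = min_particle_px,
    fill_holes = isTRUE(fill_holes)
  ), class = "pipeline_config")
}

# FNV-1a hash of a string, as 8 hex digits; used for config fingerprints
fnv1a_hex <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime 16777619, done in two halves to
    # stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Fingerprint of a pipeline configuration
#'
#' A short hash over the canonical serialized form of the configuration;
#' it changes iff any analysis-relevant setting changes, and is recorded
#' with every run for provenance.
#'
#' @param cfg a [pipeline_config()].
#' @return An 8-character hex string.
#' @export
config_fingerprint <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config") || is.list(cfg))
  canonical <- paste(
    names(cfg),
    vapply(cfg, function(v) paste(format(v, digits = 15), collapse = ","),
           character(1)),
    sep = "=", collapse = ";"
  )
  fnv1a_hex(canonical)
}

#' Run the full preprocessing and segmentation chain
#'
#' Applies, in this fixed order: [invert()] -> [rolling_ball_subtract()] ->
#' [fft_bandpass()] -> [max_entropy_threshold()] -> [binarize()]. The chain
#' is fully deterministic; intermediate stages can be retained for
#' inspection.
#'
#' Degenerate images: particles are sparse dark organelles, so the
#' thresholded foreground is expected to be a minority of the field. If
#' the chosen threshold marks more than half of the pixels as foreground,
#' no gray level separates particles from background (a featureless
#' field thresholded inside its noise); the mask is returned empty with
#' a warning.
#'
#' @param img a [gray_image()] (raw TEM polarity: dark particles on a
#'   bright background).
#' @param cfg a [pipeline_config()].
#' @param keep_stages retain intermediate images in the result.
#' @return A list of class `preprocess_result` with elements `mask`
#'   (logical matrix), `threshold`, `fingerprint`, and (with
#'   `keep_stages = TRUE`) `stages` (named list of intermediate
#'   [gray_image()]s).
#' @export
run_preprocess <- function(img, cfg = pipeline_config(), keep_stages = FALSE) {
  stopifnot(is_gray_image(img), inherits(cfg, "pipeline_config"))
  inv <- invert(img)
  rb <- rolling_ball_subtract(inv, cfg$rolling_ball_radius)
  bp <- fft_bandpass(rb, large = cfg$bandpass_large, small = cfg$bandpass_small,
                     stripe_direction = cfg$stripe_direction,
                     tolerance_pct = cfg$stripe_tolerance)
  thr <- max_entropy_threshold(bp)
  mask <- binarize(bp, thr)
  if (mean(mask) > 0.5) {
    warning("thresholded foreground covers most of the field: ",
            "treating the image as featureless (empty mask)")
    mask[] <- FALSE
  }
  out <- list(
    mask = mask,
    threshold = thr,
    fingerprint = config_fingerprint(cfg)
  )
  if (keep_stages)
    out$stages <- list(inverted = inv, background_subtracted = rb,
                       bandpassed = bp)
  structure(out, class = "preprocess_result")
}
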