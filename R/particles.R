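#' Label connected particles
#'
#' Connected-component labeling of a binary mask under 8-connectivity
#' (diagonal neighbours connect, the reference particle-analysis default).
#' Labels are dense from 1.
#'
#' @param mask logical matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
label_particles <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  .cpp_label8(mask)
}

#' Strict particle size filter
#'
#' Retains particles whose pixel count is strictly greater than `min_px`
#' ("greater than 600 pixels" is an exclusive bound: a 600 px particle is
#' dropped, a 601 px particle is kept).
#'
#' @param labels integer label matrix from [label_particles()].
#' @param min_px exclusive lower bound on pixel count (default 600).
#' @return Integer label matrix with surviving particles relabeled densely
#'   from 1; the mapping old -> new is in `attr(, "kept_labels")`.
#' @export
filter_by_size <- function(labels, min_px = 600) {
  stopifnot(is.matrix(labels), min_px >= 0)
  n <- max(labels)
  if (n == 0) {
    attr(labels, "kept_labels") <- integer(0)
    return(labels)
  }
  sizes <- tabulate(labels[labels > 0], nbins = n)
  keep <- which(sizes > min_px)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  fg <- labels > 0
  out[fg] <- map[labels[fg]]
  attr(out, "kept_labels") <- keep
  out
}

# Perimeter of a traced boundary path using the Vossepoel-Smeulders
# chain-code weights: 0.980 per straight step, 1.406 per diagonal step,
# -0.091 per corner (direction change). Single-pixel particles use the
# unit-square convention (perimeter 4).
perimeter_from_path <- function(path) {
  n <- nrow(path)
  if (n == 1) return(4)
  nxt <- c(2:n, 1)
  dr <- path[nxt, 1] - path[, 1]
  dc <- path[nxt, 2] - path[, 2]
  diag_step <- abs(dr) == 1 & abs(dc) == 1
  code <- atan2(dr, dc)
  corners <- sum(code != code[c(n, seq_len(n - 1))])
  0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * corners
}

# Maximum caliper (Feret) diameter over the convex hull of pixel centers.
# Single-pixel particles have Feret 0 under the pixel-center convention.
feret_from_points <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  m <- length(h)
  if (m == 1) return(0)
  best <- 0
  for (i in seq_len(m - 1)) {
    d2 <- (hx[(i + 1):m] - hx[i])^2 + (hy[(i + 1):m] - hy[i])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

#' Measure one particle
#'
#' Computes the morphological parameter set for a single labeled particle:
#' * `area`: pixel count (px^2), and `area_sq = area^2`;
#' * `perimeter`: length of the traced outer boundary with
#'   corner-smoothing chain-code weights (see Details);
#' * `major`/`minor`: axes of the ellipse with the same second central
#'   moments as the pixel set (each pixel treated as a unit square, i.e.
#'   a 1/12 variance term is added); degenerate (collinear) pixel sets get
#'   a 1 px minor-axis floor and are flagged;
#' * `feret`: maximum caliper distance over convex-hull vertices of the
#'   pixel centers;
#' * `circularity = min(1, 4*pi*area/perimeter^2)` (capped at 1);
#' * `form_factor = perimeter^2/(4*pi*area)` (uncapped, so
#'   `form_factor * (4*pi*area/perimeter^2) = 1` identically);
#' * `roundness = 4*area/(pi*major^2)`;
#' * `aspect_ratio = major/minor`.
#'
#' Boundary steps are weighted 0.980 (straight), 1.406 (diagonal) with a
#' -0.091 corner correction, an unbiased digital perimeter estimator.
#'
#' @param labels integer label matrix.
#' @param id particle label to measure.
#' @param pixel_size optional nm/px; when given, `area_nm2`, `perimeter_nm`
#'   and `feret_nm` are added.
#' @return A one-row data.frame.
#' @export
measure_particle <- function(labels, id, pixel_size = NA_real_) {
  idx <- which(labels == id, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("particle id not present")
  area <- nrow(idx)
  x <- idx[, 2]; y <- idx[, 1]
  path <- .cpp_trace_boundary(labels, as.integer(id))
  perim <- perimeter_from_path(path)

  # second central moments of the pixel set (unit-square pixels)
  mx <- mean(x); my <- mean(y)
  u20 <- mean((x - mx)^2) + 1 / 12
  u02 <- mean((y - my)^2) + 1 / 12
  u11 <- mean((x - mx) * (y - my))
  com <- (u20 + u02) / 2
  del <- sqrt(((u20 - u02) / 2)^2 + u11^2)
  l1 <- com + del
  l2 <- max(com - del, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  degenerate <- FALSE
  if (minor < 1) {
    minor <- 1
    degenerate <- TRUE
  }

  feret <- feret_from_points(x, y)
  circ_raw <- 4 * pi * area / perim^2
  out <- data.frame(
    particle = as.integer(id),
    area = area,
    area_sq = area^2,
    perimeter = perim,
    major = major,
    minor = minor,
    feret = feret,
    circularity = min(1, circ_raw),
    roundness = 4 * area / (pi * major^2),
    aspect_ratio = major / minor,
    form_factor = perim^2 / (4 * pi * area),
    centroid_x = mx,
    centroid_y = my,
    degenerate = degenerate
  )
  if (!is.na(pixel_size)) {
    out$area_nm2 <- area * pixel_size^2
    out$perimeter_nm <- perim * pixel_size
    out$feret_nm <- feret * pixel_size
  }
  out
}

fill_mask_holes <- function(mask) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("hole filling requires the EBImage package")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  as.matrix(EBImage::fillHull(lab)) > 0
}

#' Measure all particles in a masked image
#'
#' Applies the ROI restriction, labels the mask (8-connectivity), drops
#' particles not strictly larger than `cfg$min_particle_px`, optionally
#' fills holes, and measures every survivor. The >600 px filter is applied
#' after ROI clipping.
#'
#' @param mask logical matrix from [run_preprocess()].
#' @param rois a [roi_set()], or `NULL` to analyze the whole image.
#' @param cfg a [pipeline_config()] (supplies `min_particle_px` and
#'   `fill_holes`).
#' @param image_id,condition identifiers attached to every record; the
#'   image is the cell, the statistical unit downstream.
#' @param pixel_size optional nm/px.
#' @return A data.frame with one row per retained particle (possibly
#'   zero rows).
#' @export
measure_image <- function(mask, rois = NULL, cfg = pipeline_config(),
                          image_id = NA_character_,
                          condition = NA_character_,
                          pixel_size = NA_real_) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!is.null(rois)) mask <- apply_roi(mask, rois)
  if (isTRUE(cfg$fill_holes)) mask <- fill_mask_holes(mask)
  labels <- filter_by_size(label_particles(mask), cfg$min_particle_px)
  n <- max(labels)
  if (n == 0) {
    out <- measure_particle(matrix(c(1L, 0L), 1), 1)[0, ]
  } else {
    out <- do.call(rbind, lapply(seq_len(n), function(i)
      measure_particle(labels, i, pixel_size)))
  }
  cbind(data.frame(image_id = rep(image_id, nrow(out)),
                   condition = rep(condition, nrow(out)),
                   stringsAsFactors = FALSE), out)
}
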