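#' Region-of-interest polygon set
#'
#' ROIs are drawn on the unprocessed micrograph around mitochondria,
#' excluding the plasma membrane and other high-contrast regions; particle
#' analysis is restricted to their union.
#'
#' @param polygons list of polygons; each a numeric matrix or data.frame
#'   with columns x, y (pixel coordinates, >= 3 vertices, simple).
#' @param image_id optional image identifier.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(polygons, image_id = NA_character_) {
  if (!is.list(polygons) || length(polygons) == 0)
    stop("'polygons' must be a non-empty list")
  polys <- lapply(polygons, function(p) {
    p <- as.matrix(as.data.frame(p))
    if (ncol(p) != 2) stop("each polygon needs two columns (x, y)")
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    if (nrow(p) < 3) stop("each polygon needs at least 3 vertices")
    p
  })
  structure(list(polygons = polys, image_id = image_id), class = "roi_set")
}

#' Read/write ROI polygons as JSON
#'
#' Schema: `{"image_id": "...", "polygons": [[[x, y], ...], ...]}` with
#' pixel coordinates.
#'
#' @param path JSON file path.
#' @return [read_roi_json()]: a [roi_set()]; [write_roi_json()]: `path`.
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  polys <- obj$polygons
  if (is.array(polys) && length(dim(polys)) == 3) {
    polys <- lapply(seq_len(dim(polys)[1]), function(i) polys[i, , ])
  }
  roi_set(lapply(polys, function(p) {
    m <- matrix(unlist(p), ncol = 2, byrow = FALSE)
    m
  }), image_id = if (!is.null(obj$image_id)) obj$image_id else NA_character_)
}

#' @rdname read_roi_json
#' @param rois a [roi_set()].
#' @export
write_roi_json <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  obj <- list(
    image_id = rois$image_id,
    polygons = lapply(rois$polygons, function(p) unname(p))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Boundary-inclusive point-in-polygon test (even-odd rule), vectorized
# over points. Points exactly on an edge count as inside.
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  vx <- poly[, 1]; vy <- poly[, 2]
  nv <- length(vx)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # on-segment check: collinear and within the segment's bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    seg <- abs(cross) <= eps * (abs(xj - xi) + abs(yj - yi) + 1) &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    onedge <- onedge | seg
    j <- i
  }
  inside | onedge
}

#' Restrict a binary mask to ROI polygons
#'
#' Foreground outside the union of the ROI polygons is set to background;
#' inside it is unchanged. Pixel membership is decided at pixel centers
#' (pixel (row r, col c) has center x = c, y = r) and is
#' boundary-inclusive.
#'
#' @param mask logical matrix.
#' @param rois a [roi_set()]; an empty or missing set is an error, which
#'   distinguishes "no ROI supplied" from "keep the whole image".
#' @return The clipped logical mask.
#' @export
apply_roi <- function(mask, rois) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (missing(rois) || is.null(rois) ||
      !inherits(rois, "roi_set") || length(rois$polygons) == 0)
    stop("an ROI set with at least one polygon is required")
  nr <- nrow(mask); nc <- ncol(mask)
  keep <- matrix(FALSE, nr, nc)
  for (poly in rois$polygons) {
    if (any(poly[, 1] < 0 | poly[, 1] > nc + 1 |
            poly[, 2] < 0 | poly[, 2] > nr + 1))
      stop("ROI polygon extends outside the image bounds")
    cmin <- max(1L, floor(min(poly[, 1])))
    cmax <- min(nc, ceiling(max(poly[, 1])))
    rmin <- max(1L, floor(min(poly[, 2])))
    rmax <- min(nr, ceiling(max(poly[, 2])))
    if (cmin > cmax || rmin > rmax) next
    cols <- cmin:cmax
    rows <- rmin:rmax
    grid <- expand.grid(r = rows, c = cols)
    hit <- point_in_polygon(grid$c, grid$r, poly)
    if (any(hit))
      keep[cbind(grid$r[hit], grid$c[hit])] <- TRUE
  }
  mask & keep
}

#' Read ROI polygons from a CSV vertex list
#'
#' Schema: columns `polygon` (identifier grouping vertices), `x`, `y`
#' (pixel coordinates), vertices in drawing order.
#'
#' @param path CSV file path.
#' @param image_id optional image identifier to attach.
#' @return A [roi_set()].
#' @export
read_roi_csv <- function(path, image_id = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("polygon", "x", "y")
  if (!all(need %in% names(df)))
    stop("ROI CSV needs columns ", paste(need, collapse = ", "))
  roi_set(lapply(split(df, df$polygon), function(p) cbind(p$x, p$y)),
          image_id = image_id)
}
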