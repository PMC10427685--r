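# Ramanujan's second approximation to the ellipse perimeter; relative
# error below 1e-6 for aspect ratios up to 10.
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Analytic morphology of an ellipse with semi-axes a >= b
ellipse_truth <- function(a, b) {
  area <- pi * a * b
  perim <- ellipse_perimeter(a, b)
  data.frame(
    true_area = area,
    true_perimeter = perim,
    true_major = 2 * a,
    true_minor = 2 * b,
    true_feret = 2 * a,
    true_circularity = 4 * pi * area / perim^2,
    true_roundness = b / a,
    true_aspect_ratio = a / b,
    true_form_factor = perim^2 / (4 * pi * area)
  )
}

#' Specify a synthetic micrograph scene
#'
#' Describes a TEM-like scene: dark elliptical particles (the
#' electron-dense mitochondria) on a bright textured background with a
#' slow illumination gradient, additive Gaussian noise, optional vertical
#' scan-line stripes, and an optional large dark band emulating the plasma
#' membrane (a high-contrast region to be excluded by ROIs).
#'
#' Amplitudes are fractions of the dynamic range. The same spec and seed
#' always render to the identical raster.
#'
#' @param width,height image size in px (>= 64 for the FFT stages).
#' @param depth bit depth (8 or 16).
#' @param particles data.frame with columns `cx, cy` (center, px),
#'   `a, b` (semi-major/minor, px, `a >= b > 0`), `theta` (orientation,
#'   radians), `intensity` (darkening, fraction of dynamic range). May have
#'   zero rows.
#' @param background_level background intensity as a fraction (default 0.7).
#' @param gradient_amplitude peak-to-peak diagonal illumination gradient,
#'   fraction of range.
#' @param noise_sd Gaussian noise SD, fraction of range.
#' @param stripe_amplitude,stripe_period vertical stripe sinusoid
#'   (intensity varies along x); period in px, must be > 0.
#' @param membrane_band add a dark high-contrast band along the left edge.
#' @param seed integer RNG seed for the noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 160, height = 160, depth = 8L,
                       particles = empty_particles(),
                       background_level = 0.7,
                       gradient_amplitude = 0.05,
                       noise_sd = 0.02,
                       stripe_amplitude = 0,
                       stripe_period = 12,
                       membrane_band = FALSE,
                       seed = 1L) {
  particles <- as.data.frame(particles)
  need <- c("cx", "cy", "a", "b", "theta", "intensity")
  if (!all(need %in% names(particles)))
    stop("'particles' needs columns ", paste(need, collapse = ", "))
  if (nrow(particles) > 0) {
    with(particles, {
      if (any(b <= 0) || any(a < b)) stop("need a >= b > 0 for every particle")
      if (any(intensity <= 0 | intensity > 1))
        stop("particle intensity must be in (0, 1]")
    })
    # bounding-circle containment check (conservative)
    marg <- 2
    out_of_bounds <- with(particles,
      cx - a < marg | cx + a > width - marg + 1 |
      cy - a < marg | cy + a > height - marg + 1)
    if (any(out_of_bounds))
      stop("particle(s) ", paste(which(out_of_bounds), collapse = ", "),
           " extend outside the image bounds")
    if (nrow(particles) > 1) {
      d <- as.matrix(dist(particles[, c("cx", "cy")]))
      lim <- outer(particles$a, particles$a, "+")
      diag(d) <- Inf
      if (any(d < lim)) stop("planted particles overlap")
    }
  }
  if (stripe_period <= 0) stop("'stripe_period' must be > 0")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    depth = as.integer(depth), particles = particles,
    background_level = background_level,
    gradient_amplitude = gradient_amplitude,
    noise_sd = noise_sd,
    stripe_amplitude = stripe_amplitude,
    stripe_period = stripe_period,
    membrane_band = isTRUE(membrane_band),
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Empty particle table for [scene_spec()]
#' @return A zero-row data.frame with the particle columns.
#' @export
empty_particles <- function() {
  data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
             b = numeric(0), theta = numeric(0), intensity = numeric(0))
}

# Anti-aliased coverage of one ellipse over the full pixel grid.
# Pixels whose center is clearly inside get 1, clearly outside 0; pixels
# in a band around the boundary are 4x4 supersampled, so the summed
# coverage converges to the analytic area.
ellipse_coverage <- function(width, height, cx, cy, a, b, theta) {
  cov <- matrix(0, height, width)
  pad <- 2
  c0 <- max(1L, floor(cx - a - pad)); c1 <- min(width, ceiling(cx + a + pad))
  r0 <- max(1L, floor(cy - a - pad)); r1 <- min(height, ceiling(cy + a + pad))
  xs <- c0:c1; ys <- r0:r1
  ct <- cos(theta); st <- sin(theta)
  rho2 <- function(px, py) {
    dx <- px - cx; dy <- py - cy
    u <- (dx * ct + dy * st) / a
    v <- (-dx * st + dy * ct) / b
    u^2 + v^2
  }
  g <- expand.grid(y = ys, x = xs)
  r2 <- rho2(g$x, g$y)
  # band half-width: one pixel expressed in rho units near the boundary
  delta <- 1.6 / min(a, b)
  inner <- sqrt(pmax(r2, 0)) <= 1 - delta
  outer <- sqrt(pmax(r2, 0)) >= 1 + delta
  band <- !(inner | outer)
  val <- as.numeric(inner)
  if (any(band)) {
    off <- (c(-3, -1, 1, 3) / 8)
    sub <- expand.grid(dy = off, dx = off)
    bx <- g$x[band]; by <- g$y[band]
    acc <- numeric(length(bx))
    for (k in seq_len(nrow(sub))) {
      acc <- acc + (rho2(bx + sub$dx[k], by + sub$dy[k]) <= 1)
    }
    val[band] <- acc / nrow(sub)
  }
  cov[cbind(g$y, g$x)] <- val
  cov
}

#' Render a synthetic micrograph
#'
#' Deterministically rasterizes a [scene_spec()]: background with diagonal
#' illumination gradient, anti-aliased dark ellipses, optional membrane
#' band, vertical stripes, and seeded Gaussian noise, rounded and clipped
#' to the bit depth. Ground-truth rows align 1:1 with `spec$particles`.
#'
#' @param spec a [scene_spec()].
#' @return A list with `image` (a [gray_image()]) and `truth` (data.frame
#'   with one row per planted particle: analytic area, perimeter
#'   (Ramanujan), major/minor, Feret `= 2a`, circularity, roundness,
#'   aspect ratio, form factor, and the planted center).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width; h <- spec$height
  maxv <- 2^spec$depth - 1
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  img <- maxv * (spec$background_level +
    spec$gradient_amplitude * ((xs / w + ys / h) / 2 - 0.5))

  p <- spec$particles
  if (nrow(p) > 0) {
    for (i in seq_len(nrow(p))) {
      cov <- ellipse_coverage(w, h, p$cx[i], p$cy[i], p$a[i], p$b[i],
                              p$theta[i])
      img <- img - maxv * p$intensity[i] * cov
    }
  }
  if (spec$membrane_band) {
    # dark, high-contrast band hugging the left edge (plasma membrane)
    bandw <- max(8L, round(w * 0.08))
    img[, seq_len(bandw)] <- 0.06 * maxv
  }
  if (spec$stripe_amplitude > 0) {
    img <- img + maxv * spec$stripe_amplitude *
      sin(2 * pi * xs / spec$stripe_period)
  }
  if (spec$noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(spec$seed)
    img <- img + matrix(rnorm(w * h, 0, spec$noise_sd * maxv), h, w)
  }
  img <- round(pmin(pmax(img, 0), maxv))
  truth <- if (nrow(p) > 0) {
    cbind(data.frame(particle = seq_len(nrow(p)), cx = p$cx, cy = p$cy),
          do.call(rbind, lapply(seq_len(nrow(p)),
                                function(i) ellipse_truth(p$a[i], p$b[i]))))
  } else {
    cbind(data.frame(particle = integer(0), cx = numeric(0),
                     cy = numeric(0)), ellipse_truth(1, 1)[0, ])
  }
  list(image = gray_image(img, spec$depth), truth = truth)
}

# save/restore the global RNG state so seeded generators do not clobber
# the caller's random stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Write/read a scene specification as JSON
#'
#' The spec round-trips losslessly: reading a written file reproduces a
#' spec that renders the byte-identical raster.
#'
#' @param spec a [scene_spec()].
#' @param path JSON file path.
#' @return [write_scene_spec()]: `path`, invisibly; [read_scene_spec()]:
#'   the [scene_spec()].
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  obj <- jsonlite::fromJSON(path)
  particles <- as.data.frame(obj$particles)
  if (nrow(particles) == 0) particles <- empty_particles()
  scene_spec(width = obj$width, height = obj$height, depth = obj$depth,
             particles = particles,
             background_level = obj$background_level,
             gradient_amplitude = obj$gradient_amplitude,
             noise_sd = obj$noise_sd,
             stripe_amplitude = obj$stripe_amplitude,
             stripe_period = obj$stripe_period,
             membrane_band = obj$membrane_band,
             seed = obj$seed)
}
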