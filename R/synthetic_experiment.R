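# Deterministic per-image seed derived from the master seed and image
# index; kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) %% 65536 * 31397 +
                as.numeric(index) * 9973 + 12345) %% 2147483647)
}

#' Generate a multi-condition synthetic TEM experiment
#'
#' Emulates the study design (a set of cells imaged per condition, one
#' micrograph per cell) with a controlled treatment effect: the treated
#' condition draws particle semi-axes scaled by `sqrt(1 - size_shift)`, so
#' its expected mitochondrial area is `(1 - size_shift)` times the control
#' mean while shape (aspect ratio) is unchanged. Particle placement uses
#' rejection sampling (up to 1000 retries) to keep planted particles
#' non-overlapping; per-image seeds derive deterministically from the
#' master seed, so the same master seed reproduces the identical image
#' set.
#'
#' Control particles have semi-minor axis b ~ U(16.5, 19) px and aspect
#' ratio a/b ~ U(1.1, 1.6), so even after a 30% area reduction every
#' planted particle stays above the 600 px analysis filter and the size
#' filter does not truncate the treated distribution.
#'
#' @param n_cells_per_condition number of cells (images) per condition
#'   (at least 2).
#' @param size_shift fractional mean-area reduction in the treated
#'   condition, in `[0, 1)`.
#' @param seed master seed.
#' @param conditions character vector of two condition labels
#'   (control first).
#' @param n_particles particles planted per cell.
#' @param width,height image size in px.
#' @param noise_sd,gradient_amplitude,stripe_amplitude,stripe_period scene
#'   nuisance parameters, passed to [scene_spec()].
#' @param render if `FALSE`, skip rasterization and return ground truth
#'   only (fast path for distributional checks).
#' @return A list of class `synthetic_experiment`: `cells` (list with one
#'   entry per cell: `image_id`, `condition`, `spec`, `image` (or `NULL`),
#'   `truth`), and `truth` (the row-bound ground-truth table with
#'   `image_id` and `condition`).
#' @export
generate_experiment <- function(n_cells_per_condition = 25,
                                size_shift = 0.3,
                                seed = 1L,
                                conditions = c("control", "treated"),
                                n_particles = 3,
                                width = 160, height = 160,
                                noise_sd = 0.02,
                                gradient_amplitude = 0.05,
                                stripe_amplitude = 0.03,
                                stripe_period = 12,
                                render = TRUE) {
  if (n_cells_per_condition < 2) stop("need >= 2 cells per condition")
  if (size_shift < 0 || size_shift >= 1) stop("'size_shift' must be in [0, 1)")
  stopifnot(length(conditions) == 2)
  axis_scale <- c(1, sqrt(1 - size_shift))
  cells <- list()
  idx <- 0L
  for (ci in seq_along(conditions)) {
    for (cell in seq_len(n_cells_per_condition)) {
      idx <- idx + 1L
      img_seed <- derive_seed(seed, idx)
      old <- get_rng_state()
      set.seed(img_seed)
      parts <- place_particles(n_particles, width, height,
                               axis_scale = axis_scale[ci])
      restore_rng_state(old)
      spec <- scene_spec(
        width = width, height = height, particles = parts,
        noise_sd = noise_sd, gradient_amplitude = gradient_amplitude,
        stripe_amplitude = stripe_amplitude, stripe_period = stripe_period,
        seed = img_seed
      )
      image_id <- sprintf("%s_cell%02d", conditions[ci], cell)
      rendered <- if (render) render_scene(spec) else NULL
      truth <- if (render) {
        rendered$truth
      } else {
        cbind(data.frame(particle = seq_len(nrow(parts)),
                         cx = parts$cx, cy = parts$cy),
              do.call(rbind, lapply(seq_len(nrow(parts)), function(i)
                ellipse_truth(parts$a[i], parts$b[i]))))
      }
      truth$image_id <- image_id
      truth$condition <- conditions[ci]
      cells[[idx]] <- list(
        image_id = image_id, condition = conditions[ci], spec = spec,
        image = if (render) rendered$image else NULL, truth = truth
      )
    }
  }
  structure(list(
    cells = cells,
    truth = do.call(rbind, lapply(cells, `[[`, "truth")),
    conditions = conditions,
    seed = seed, size_shift = size_shift
  ), class = "synthetic_experiment")
}

# Rejection-sample non-overlapping ellipses (bounding-circle criterion)
place_particles <- function(n, width, height, axis_scale = 1,
                            b_range = c(16.5, 19), ar_range = c(1.1, 1.6),
                            intensity_range = c(0.32, 0.4),
                            max_retries = 1000) {
  parts <- empty_particles()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      b <- runif(1, b_range[1], b_range[2]) * axis_scale
      a <- b * runif(1, ar_range[1], ar_range[2])
      marg <- a + 3
      cx <- runif(1, marg, width - marg)
      cy <- runif(1, marg, height - marg)
      ok <- TRUE
      if (nrow(parts) > 0) {
        d <- sqrt((parts$cx - cx)^2 + (parts$cy - cy)^2)
        ok <- all(d >= parts$a + a + 1)
      }
      if (ok) {
        parts <- rbind(parts, data.frame(
          cx = cx, cy = cy, a = a, b = b,
          theta = runif(1, 0, pi),
          intensity = runif(1, intensity_range[1], intensity_range[2])
        ))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping particles after ",
           max_retries, " retries")
  }
  parts
}
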