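# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results from first principles and stay
# independent of the package's implementation paths.

# Grayscale opening with a ball structuring element by direct double loop
# (only viable on small images); mirrors the documented edge convention:
# out-of-image offsets are ignored.
brute_rolling_ball <- function(mat, radius) {
  nr <- nrow(mat); nc <- ncol(mat)
  r <- floor(radius)
  offs <- expand.grid(dv = -r:r, du = -r:r)
  offs <- offs[offs$du^2 + offs$dv^2 <= radius^2, ]
  offs$k <- sqrt(radius^2 - offs$du^2 - offs$dv^2)
  ero <- matrix(NA_real_, nr, nc)
  for (c in 1:nc) for (rr in 1:nr) {
    v <- Inf
    for (i in seq_len(nrow(offs))) {
      r2 <- rr + offs$dv[i]; c2 <- c + offs$du[i]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
        v <- min(v, mat[r2, c2] - offs$k[i])
    }
    ero[rr, c] <- v
  }
  dil <- matrix(NA_real_, nr, nc)
  for (c in 1:nc) for (rr in 1:nr) {
    v <- -Inf
    for (i in seq_len(nrow(offs))) {
      r2 <- rr + offs$dv[i]; c2 <- c + offs$du[i]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
        v <- max(v, ero[r2, c2] + offs$k[i])
    }
    dil[rr, c] <- v
  }
  dil
}

# Kapur maximum-entropy objective evaluated by direct summation for every
# candidate threshold; returns the 0-based argmax (lowest on ties).
brute_max_entropy <- function(counts) {
  p <- counts / sum(counts)
  n <- length(p)
  best <- -Inf; best_t <- NA
  for (t0 in 0:(n - 2)) {
    bg <- p[1:(t0 + 1)]; fg <- p[(t0 + 2):n]
    pt <- sum(bg)
    if (pt <= 0 || pt >= 1) next
    q <- bg[bg > 0] / pt
    hb <- -sum(q * log(q))
    q <- fg[fg > 0] / (1 - pt)
    hf <- -sum(q * log(q))
    if (hb + hf > best + 1e-12) { best <- hb + hf; best_t <- t0 }
  }
  best_t
}

# O(n^2) Feret oracle over all pixel centers
brute_feret <- function(x, y) {
  n <- length(x)
  if (n == 1) return(0)
  best <- 0
  for (i in 1:(n - 1)) {
    d2 <- (x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Ellipse arc length by numerical quadrature (independent of Ramanujan)
quadrature_ellipse_perimeter <- function(a, b) {
  f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  4 * stats::integrate(f, 0, pi / 2, rel.tol = 1e-12)$value
}

# Label matrix holding a single particle given by pixel (row, col) indices
label_matrix <- function(nr, nc, rows, cols) {
  m <- matrix(0L, nr, nc)
  m[cbind(rows, cols)] <- 1L
  m
}

# Digital ellipse: pixel centers with normalized radius <= 1
digital_ellipse_mask <- function(nr, nc, cx, cy, a, b, theta = 0) {
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  dx <- xs - cx; dy <- ys - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u^2 + v^2 <= 1
}

# One-particle scene with configurable nuisance terms
one_particle_scene <- function(a, b, theta = 0, noise = 0, gradient = 0,
                               stripes = 0, seed = 3L, size = 160) {
  p <- data.frame(cx = size / 2, cy = size / 2, a = a, b = b,
                  theta = theta, intensity = 0.35)
  render_scene(scene_spec(width = size, height = size, particles = p,
                          noise_sd = noise, gradient_amplitude = gradient,
                          stripe_amplitude = stripes, seed = seed))
}

# Amplitude of a (filtered) sinusoid pattern, measured away from borders
central_amplitude <- function(img, margin = 32) {
  d <- img$data
  sub <- d[(margin + 1):(nrow(d) - margin), (margin + 1):(ncol(d) - margin)]
  (max(sub) - min(sub)) / 2
}

# Sinusoid test image: intensity varies along x ("vertical stripes") or
# along y ("horizontal stripes")
sinusoid_image <- function(n = 256, period, amplitude = 40, along = "x") {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  phase <- if (along == "x") xs else ys
  gray_image(round(128 + amplitude * sin(2 * pi * phase / period)), 8L)
}
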