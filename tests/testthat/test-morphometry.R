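test_that("ROI clipping follows pixel-center, boundary-inclusive rules", {
  mask <- matrix(FALSE, 100, 100)
  mask[21:60, 21:60] <- TRUE # 40x40 block

  whole <- roi_set(list(cbind(c(0.5, 100.5, 100.5, 0.5),
                              c(0.5, 0.5, 100.5, 100.5))))
  expect_identical(apply_roi(mask, whole), mask)

  far <- roi_set(list(cbind(c(70, 95, 95, 70), c(70, 70, 95, 95))))
  expect_false(any(apply_roi(mask, far)))

  # rectangle keeping columns 1..40 clips the block to 20 x 40 = 800 px
  half <- roi_set(list(cbind(c(0.5, 40.5, 40.5, 0.5),
                             c(0.5, 0.5, 100.5, 100.5))))
  expect_equal(sum(apply_roi(mask, half)), 800)

  expect_error(apply_roi(mask, NULL), "ROI")
  expect_error(roi_set(list()), "non-empty")
})

test_that("labeling uses 8-connectivity with dense labels", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE # diagonal touch: one particle
  expect_equal(max(label_particles(m)), 1)

  expect_equal(max(label_particles(matrix(FALSE, 5, 5))), 0)

  m3 <- matrix(FALSE, 20, 20)
  m3[2:4, 2:4] <- TRUE; m3[10:12, 10:12] <- TRUE; m3[16:18, 2:4] <- TRUE
  lab <- label_particles(m3)
  expect_equal(max(lab), 3)
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L, 2L, 3L))
})

test_that("the size filter bound is strict (greater than, not at least)", {
  # 600 px (24 x 25) and 601 px particles side by side
  m <- matrix(FALSE, 80, 80)
  m[2:25, 2:26] <- TRUE            # 24 x 25 = 600 px
  m[40:63, 40:64] <- TRUE          # 600 px
  m[40, 65] <- TRUE                # +1 -> 601 px
  lab <- filter_by_size(label_particles(m), 600)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab == 1), 601)

  # min_px = 0 keeps every non-empty particle
  lab0 <- filter_by_size(label_particles(m), 0)
  expect_equal(max(lab0), 2)

  # mixed sizes: {100, 650, 3000} with the 600 px bound keeps 2
  m2 <- matrix(FALSE, 120, 200)
  m2[2:11, 2:11] <- TRUE       # 100
  m2[20:45, 30:54] <- TRUE     # 26 x 25 = 650
  m2[61:110, 61:120] <- TRUE   # 50 x 60 = 3000
  expect_equal(max(filter_by_size(label_particles(m2), 600)), 2)
})

test_that("digital disk measurements match the analytic circle", {
  mask <- digital_ellipse_mask(100, 100, 50, 50, 30, 30)
  lab <- label_particles(mask)
  m <- measure_particle(lab, 1)
  expect_equal(m$area, pi * 900, tolerance = 0.02)
  expect_gte(m$circularity, 0.9)
  expect_equal(m$aspect_ratio, 1, tolerance = 0.05)
  expect_equal(m$feret, 60, tolerance = 0.02)
  # uncapped identity: form factor is exactly the reciprocal shape term
  expect_identical(m$form_factor * (4 * pi * m$area / m$perimeter^2), 1)
  expect_equal(m$roundness, 1, tolerance = 0.05)
  # perimeter estimator is close to the true circumference
  expect_equal(m$perimeter, 2 * pi * 30, tolerance = 0.02)
})

test_that("Feret follows the pixel-center convention", {
  # two pixels at centers (0,0) and (3,4): a 3-4-5 triangle
  lab <- label_matrix(8, 8, rows = c(1, 5), cols = c(1, 4))
  m <- measure_particle(lab, 1)
  expect_equal(m$feret, 5)
  # single pixel: Feret 0 under this convention
  expect_equal(measure_particle(label_matrix(5, 5, 3, 3), 1)$feret, 0)
})

test_that("Feret equals the brute-force pairwise maximum on 50 particles", {
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 3, 14); b <- runif(1, 2, a); th <- runif(1, 0, pi)
    cx <- runif(1, 18, 22); cy <- runif(1, 18, 22)
    mask <- digital_ellipse_mask(40, 40, cx, cy, a, b, th)
    if (!any(mask)) next
    lab <- label_particles(mask)
    idx <- which(lab == 1, arr.ind = TRUE)
    m <- measure_particle(lab, 1)
    expect_equal(m$feret, brute_feret(idx[, 2], idx[, 1]), tolerance = 1e-9)
  }
})

test_that("measurements are translation-invariant and rotation-stable", {
  mask <- digital_ellipse_mask(120, 120, 45.3, 41.7, 22, 13, 0.6)
  base <- measure_particle(label_particles(mask), 1)

  shifted <- matrix(FALSE, 120, 120)
  shifted[31:120, 26:120] <- mask[1:90, 1:95] # shift by (+30, +25)
  ms <- measure_particle(label_particles(shifted), 1)
  for (p in c("area", "perimeter", "major", "minor", "feret",
              "circularity", "roundness", "aspect_ratio", "form_factor")) {
    expect_identical(ms[[p]], base[[p]])
  }

  rotated <- t(mask)[, rev(seq_len(120))] # 90 degree rotation
  mr <- measure_particle(label_particles(rotated), 1)
  expect_identical(mr$area, base$area)
  expect_equal(mr$feret, base$feret, tolerance = 1e-9)
  expect_equal(mr$aspect_ratio, base$aspect_ratio, tolerance = 1e-9)
  expect_equal(mr$perimeter, base$perimeter, tolerance = 0.01)
  expect_equal(mr$circularity, base$circularity, tolerance = 0.01)
})

test_that("measured area scales as the square of the axis scale", {
  for (s in c(1.25, 1.5, 2)) {
    m1 <- measure_particle(label_particles(
      digital_ellipse_mask(200, 200, 100, 100, 16, 13, 0.4)), 1)
    m2 <- measure_particle(label_particles(
      digital_ellipse_mask(200, 200, 100, 100, 16 * s, 13 * s, 0.4)), 1)
    expect_equal(m2$area / m1$area, s^2, tolerance = 0.02)
  }
})

test_that("measure_image composes ROI, labeling, filtering and measurement", {
  ex <- generate_experiment(n_cells_per_condition = 2, size_shift = 0,
                            seed = 21, n_particles = 3, render = FALSE)
  cell <- ex$cells[[1]]
  parts <- cell$spec$particles
  mask <- matrix(FALSE, 160, 160)
  for (i in seq_len(nrow(parts)))
    mask <- mask | digital_ellipse_mask(160, 160, parts$cx[i], parts$cy[i],
                                        parts$a[i], parts$b[i],
                                        parts$theta[i])
  rec <- measure_image(mask, NULL, pipeline_config(),
                       image_id = cell$image_id, condition = cell$condition)
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$area > 600))
  # rasterized areas agree with analytic truth to within 5%
  got <- sort(rec$area)
  want <- sort(cell$truth$true_area)
  expect_true(all(abs(got - want) / want < 0.05))

  # a 500 px particle yields no records under the default filter
  small <- digital_ellipse_mask(80, 80, 40, 40, 14, 11, 0) # ~483 px
  expect_lt(sum(small), 600)
  rec2 <- measure_image(small, NULL, pipeline_config(),
                        image_id = "x", condition = "c")
  expect_equal(nrow(rec2), 0)
})
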