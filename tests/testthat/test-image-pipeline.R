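test_that("inversion is the involution v -> maxval - v", {
  img <- gray_image(matrix(0, 16, 16), 8L)
  expect_true(all(invert(img)$data == 255))
  img2 <- gray_image(matrix(100, 16, 16), 8L)
  expect_true(all(invert(img2)$data == 155))
  set.seed(1)
  img3 <- gray_image(matrix(as.numeric(sample(0:255, 256, TRUE)), 16, 16),
                     8L)
  expect_identical(invert(invert(img3))$data, img3$data)
})

test_that("rolling ball equals the brute-force ball opening", {
  set.seed(42)
  mat <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  img <- gray_image(mat, 8L)
  bg_oracle <- brute_rolling_ball(mat, 8)
  expect_true(all(bg_oracle <= mat + 1e-9)) # opening never exceeds image
  got <- rolling_ball_subtract(img, 8)
  expect_equal(got$data, pmax(round(mat - bg_oracle), 0), tolerance = 1e-12)
})

test_that("rolling ball removes flat and slowly varying backgrounds", {
  img <- gray_image(matrix(77, 80, 80), 8L)
  expect_true(all(rolling_ball_subtract(img, 60)$data == 0))

  # small bright square on a flat background survives intact
  mat <- matrix(50, 80, 80)
  mat[38:42, 38:42] <- 150
  out <- rolling_ball_subtract(gray_image(mat, 8L), 60)$data
  expect_true(all(abs(out[38:42, 38:42] - 100) <= 9)) # ball penetration
  expect_true(all(out[1:20, 1:20] == 0))

  # gentle ramp: residual below 5% of the ramp amplitude
  ramp <- matrix(rep(seq(40, 80, length.out = 100), each = 100), 100, 100,
                 byrow = FALSE)
  resid <- rolling_ball_subtract(gray_image(round(ramp), 8L), 30)$data
  expect_lt(max(resid[31:70, 31:70]), 0.05 * 40) # away from border effects

  expect_error(rolling_ball_subtract(img, 500), "radius")
})

test_that("bandpass gain matches the closed-form transfer function", {
  # in-band horizontal sinusoid (varies along y), suppression on
  img <- sinusoid_image(256, period = 20, along = "y")
  out <- fft_bandpass(img)
  g <- bandpass_gain(period = 20)
  expect_gt(g, 0.5)
  expect_equal(central_amplitude(out) / 40, g, tolerance = 0.05)

  # out-of-band long-period sinusoid is attenuated below 50%
  img_lo <- sinusoid_image(256, period = 256, along = "y")
  expect_lt(bandpass_gain(period = 256), 0.5)
  expect_lt(central_amplitude(fft_bandpass(img_lo)) / 40, 0.5)
  expect_equal(central_amplitude(fft_bandpass(img_lo)) / 40,
               bandpass_gain(period = 256), tolerance = 0.08)

  # below the small cut: strong attenuation
  img_hi <- sinusoid_image(256, period = 4, along = "y")
  expect_lt(central_amplitude(fft_bandpass(img_hi)) / 40, 0.2)

  # gain bounds at the nominal cuts
  expect_equal(bandpass_gain(period = 60), 0.5 *
                 exp(-log(2) * (8 / 60)^2), tolerance = 1e-12)
  expect_lt(bandpass_gain(period = 60), 0.5)
  expect_equal(bandpass_gain(period = 8),
               (1 - 0.6 * exp(-log(1.2) * (60 / 8)^2)) * 0.5,
               tolerance = 1e-12)
})

test_that("vertical stripe suppression removes in-band stripes", {
  stripes <- sinusoid_image(256, period = 12, along = "x")
  # suppression off: the 12 px pattern is in-band and passes
  out_off <- fft_bandpass(stripes, stripe_direction = "none")
  expect_gt(central_amplitude(out_off) / 40, 0.5)
  # suppression on: amplitude reduced by >= 90%
  out_on <- fft_bandpass(stripes, stripe_direction = "vertical")
  expect_lt(central_amplitude(out_on) / 40, 0.1)
})

test_that("maximum-entropy threshold matches the exhaustive oracle", {
  # uniform 8-bit histogram: analytic argmax at 127
  expect_identical(max_entropy_from_counts(rep(7L, 256)), 127L)
  img_u <- gray_image(matrix(rep(0:255, each = 256), 256, 256), 8L)
  expect_equal(max_entropy_threshold(img_u), 127)

  expect_error(max_entropy_threshold(gray_image(matrix(9, 64, 64), 8L)),
               "constant")

  set.seed(7)
  for (i in 1:100) {
    counts <- rpois(256, lambda = rexp(256, 1 / 20))
    if (sum(counts > 0) < 2) counts[c(3, 200)] <- counts[c(3, 200)] + 1
    expect_identical(max_entropy_from_counts(counts),
                     brute_max_entropy(counts))
  }
})

test_that("binarize applies a strict threshold with exact boundaries", {
  cb <- matrix(c(0, 255), 8, 8)
  img <- gray_image(cb, 8L)
  expect_identical(binarize(img, 127), cb == 255)
  expect_false(any(binarize(img, 255)))
  expect_true(all(binarize(img, -0 + 0) == (cb > 0)))
})

test_that("the full chain segments planted disks, with and without stripes", {
  sc <- one_particle_scene(30, 30, noise = 0, gradient = 0, stripes = 0)
  pre <- run_preprocess(sc$image, pipeline_config())
  lab <- filter_by_size(label_particles(pre$mask), 600)
  expect_equal(max(lab), 1)
  planted <- digital_ellipse_mask(160, 160, 80, 80, 30, 30)
  seg <- lab == 1
  expect_gte(sum(seg & planted) / sum(seg | planted), 0.9)

  sc2 <- one_particle_scene(30, 30, noise = 0, gradient = 0, stripes = 0.04)
  pre2 <- run_preprocess(sc2$image, pipeline_config())
  lab2 <- filter_by_size(label_particles(pre2$mask), 600)
  expect_equal(max(lab2), 1)
  seg2 <- lab2 == 1
  expect_gte(sum(seg2 & planted) / sum(seg2 | planted), 0.9)

  # empty noisy scene: nothing survives the size filter
  sc0 <- render_scene(scene_spec(width = 128, height = 128,
                                 particles = empty_particles(),
                                 noise_sd = 0.02, seed = 4L))
  expect_warning(pre0 <- run_preprocess(sc0$image, pipeline_config()),
                 "featureless")
  expect_equal(max(filter_by_size(label_particles(pre0$mask), 600)), 0)
})

test_that("the chain is deterministic and fingerprints its configuration", {
  sc <- one_particle_scene(24, 18, noise = 0.02, stripes = 0.03)
  cfg <- pipeline_config()
  m1 <- run_preprocess(sc$image, cfg)
  m2 <- run_preprocess(sc$image, cfg)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$fingerprint, m2$fingerprint)
  cfg2 <- pipeline_config(rolling_ball_radius = 50)
  expect_false(config_fingerprint(cfg2) == config_fingerprint(cfg))
  expect_identical(config_fingerprint(pipeline_config()),
                   config_fingerprint(pipeline_config()))
})
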