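test_that("config invariants are enforced", {
  expect_error(phantom_config(n_frames = 1), ">= 2")
  expect_error(phantom_config(os_axes = c(30, 30)), "contained")
  expect_error(phantom_config(cervix_axes = c(40, 40)), "bounds")
  expect_error(phantom_config(whitening_rate = 1.5), "whitening_rate")
})

test_that("zero-motion, noise-free phantoms have identical frames and masks", {
  ph <- generate_sequence(phantom_config(
    height = 48, width = 48, n_frames = 4, cervix_axes = c(16, 13),
    os_axes = c(4, 3), max_translation = 0, max_rotation = 0,
    noise_sigma = 0, illumination_jitter = 0, whitening_rate = 0, seed = 1))
  for (t in 2:4) {
    expect_equal(dice(ph$truth$masks[[t]], ph$truth$masks[[1]]), 1.0)
    expect_identical(ph$frames[[t]], ph$frames[[1]])
  }
  expect_equal(ph$truth$transforms$dy, rep(0, 4))
  expect_equal(ph$truth$transforms$rotation, rep(0, 4))
})

test_that("equal config and seed give bit-identical sequences", {
  a <- tiny_phantom(seed = 5)
  b <- tiny_phantom(seed = 5)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  c <- tiny_phantom(seed = 6)
  expect_false(identical(a$frames[[2]], c$frames[[2]]))
})

test_that("pure-translation circle overlap matches the pixel-count oracle", {
  # a circular cervix of radius 20 translated by exactly (dy = 10, dx = 0)
  cfg <- phantom_config(height = 96, width = 96, n_frames = 2,
                        cervix_axes = c(20, 20), os_axes = c(5, 5),
                        max_translation = 12, max_rotation = 0,
                        noise_sigma = 0, seed = 3)
  ph <- generate_sequence(cfg)
  # impose the exact displacement through the recorded-transform machinery
  u <- rigid_field(0, 10, 0, 96, 96, invert = TRUE)
  m1 <- ph$truth$masks[[1]]
  m2 <- warp_mask(m1, u)
  # oracle: direct pixel-count Dice of the two rasterized discs
  inter <- sum(m1 * m2)
  d_pix <- 2 * inter / (sum(m1) + sum(m2))
  expect_equal(dice(m2, m1), d_pix)
  # analytic overlap of two discs (r = 20, centre distance 10), as a sanity band
  r <- 20; d <- 10
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  d_analytic <- 2 * lens / (2 * pi * r^2)
  expect_equal(d_pix, d_analytic, tolerance = 0.02)
})

test_that("whitening profile anchors at 1 and increases monotonically", {
  cfg <- phantom_config(seed = 1)
  expect_equal(whitening_profile(1, cfg), 1.0)
  prof <- whitening_profile(1:17, cfg)
  expect_true(all(diff(prof) > 0))
  expect_equal(which.max(prof), 17L)
  # degenerate rate: flat at 1
  cfg0 <- phantom_config(whitening_rate = 0, seed = 1)
  expect_equal(whitening_profile(1:17, cfg0), rep(1, 17))
  expect_error(whitening_profile(18, cfg), "out of range")
  # intensities never exceed 1 despite brightening
  ph <- tiny_phantom(seed = 2)
  expect_true(all(sapply(ph$frames, max) <= 1))
  expect_true(all(sapply(ph$frames, min) >= 0))
  # the cervix really brightens over the sequence (noise-free check)
  ph0 <- tiny_phantom(seed = 2, noise_sigma = 0, illumination_jitter = 0,
                      max_translation = 0, max_rotation = 0)
  in1 <- mean(ph0$frames[[1]][, , 1][ph0$truth$masks[[1]] == 1])
  in5 <- mean(ph0$frames[[5]][, , 1][ph0$truth$masks[[5]] == 1])
  expect_gt(in5, in1)
})

test_that("stored masks equal the frame-1 mask transported by the recorded transform", {
  ph <- tiny_phantom(seed = 9)
  tr <- ph$truth$transforms
  expect_equal(tr$rotation[1], 0)
  expect_equal(tr$dy[1], 0)
  for (t in 2:5) {
    u <- rigid_field(tr$rotation[t], tr$dy[t], tr$dx[t], 48, 48, invert = TRUE)
    expect_identical(warp_mask(ph$truth$masks[[1]], u), ph$truth$masks[[t]])
  }
})

test_that("inverse rigid warp recovers frame 1 within interpolation tolerance", {
  ph <- tiny_phantom(seed = 4, noise_sigma = 0, illumination_jitter = 0)
  tr <- ph$truth$transforms
  for (t in 2:5) {
    u <- rigid_field(tr$rotation[t], tr$dy[t], tr$dx[t], 48, 48)
    rec <- ph$frames[[t]]
    for (ch in 1:3) rec[, , ch] <- warp(ph$frames[[t]][, , ch], u)
    expect_lt(mean(abs(rec - ph$frames[[1]])), 0.05)
  }
})

test_that("optional elastic perturbation stays consistent with its masks", {
  ph <- tiny_phantom(seed = 12, elastic_sigma = 1)
  # masks and frames were produced from the same perturbed coordinates:
  # the mask region must still cover the bright cervix area
  for (t in 2:5) {
    frame_r <- ph$frames[[t]][, , 1]
    inside <- mean(frame_r[ph$truth$masks[[t]] == 1])
    outside <- mean(frame_r[ph$truth$masks[[t]] == 0])
    expect_gt(inside, outside + 0.1)
  }
})
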