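test_that("zero field is the exact identity", {
  set.seed(1)
  img <- matrix(runif(12 * 10), 12, 10)
  expect_identical(warp(img, zero_field(12, 10)), img)
  frame <- random_frame(12, 12)
  z3 <- replicate(3, zero_field(12, 12), simplify = FALSE)
  expect_identical(warp_rgb(frame, z3), frame)
})

test_that("integer offsets match the array-shift oracle", {
  set.seed(2)
  img <- matrix(runif(100), 10, 10)
  u <- zero_field(10, 10)
  u[, , 2] <- 1  # sample one column to the right: out col j = in col j+1
  w <- warp(img, u)
  expect_equal(w[, 1:9], img[, 2:10])
  u2 <- zero_field(10, 10)
  u2[, , 1] <- 2
  w2 <- warp(img, u2)
  expect_equal(w2[1:8, ], img[3:10, ])
})

test_that("bilinear interpolation is exact on a linear ramp", {
  W <- 9
  ramp <- matrix(rep((0:(W - 1)) / (W - 1), each = 7), 7, W)
  u <- zero_field(7, W)
  u[, , 2] <- 0.5
  w <- warp(ramp, u)
  expect_equal(w[, 1:(W - 1)],
               matrix(rep(((0:(W - 2)) + 0.5) / (W - 1), each = 7), 7, W - 1),
               tolerance = 1e-12)
})

test_that("out-of-bounds sampling clamps to the border, never zero-fills", {
  img <- matrix(runif(64, min = 0.5), 8, 8)  # all intensities >= 0.5
  u <- zero_field(8, 8)
  u[, , 1] <- 30   # sample far below the image
  u[, , 2] <- -30  # and far to the left
  w <- warp(img, u)
  expect_true(all(w >= 0.5))
  expect_equal(unname(w[1, 1]), img[8, 1])  # clamped corner
})

test_that("warped intensities stay within the input range", {
  set.seed(3)
  img <- matrix(runif(15 * 15, 0.2, 0.9), 15, 15)
  for (k in 1:5) {
    u <- array(rnorm(15 * 15 * 2, 0, 3), c(15, 15, 2))
    w <- warp(img, u)
    expect_true(all(w >= min(img) - 1e-12 & w <= max(img) + 1e-12))
  }
})

test_that("per-channel fields shift each RGB plane independently", {
  frame <- random_frame(10, 10, seed = 4)
  shifts <- list(c(0, 1), c(1, 0), c(0, -1))  # (dy, dx) per channel
  fields <- lapply(shifts, function(s) {
    u <- zero_field(10, 10)
    u[, , 1] <- s[1]
    u[, , 2] <- s[2]
    u
  })
  w <- warp_rgb(frame, fields)
  expect_equal(w[, 1:9, 1], frame[, 2:10, 1])   # R shifted in columns
  expect_equal(w[1:9, , 2], frame[2:10, , 2])   # G shifted in rows
  expect_equal(w[, 2:10, 3], frame[, 1:9, 3])   # B opposite column shift
  # identical fields across channels equal channel-wise warp
  same <- replicate(3, fields[[1]], simplify = FALSE)
  w2 <- warp_rgb(frame, same)
  for (ch in 1:3) expect_equal(w2[, , ch], warp(frame[, , ch], fields[[1]]))
})

test_that("warp validates inputs", {
  img <- matrix(0, 8, 8)
  expect_error(warp(img, zero_field(8, 9)), "mismatch")
  bad <- zero_field(8, 8)
  bad[1, 1, 1] <- NaN
  expect_error(warp(img, bad), "non-finite")
  expect_error(warp_rgb(random_frame(8, 8), list(zero_field(8, 8))), "three")
})

test_that("rigid fields invert each other and transport masks consistently", {
  ph <- tiny_phantom(seed = 7, noise_sigma = 0, illumination_jitter = 0)
  tr <- ph$truth$transforms
  for (t in 2:5) {
    u_fwd <- rigid_field(tr$rotation[t], tr$dy[t], tr$dx[t], 48, 48)
    rec <- ph$frames[[t]]
    for (ch in 1:3) rec[, , ch] <- warp(ph$frames[[t]][, , ch], u_fwd)
    expect_lt(mean(abs(rec - ph$frames[[1]])), 0.05)
  }
})

test_that("fields round-trip through the text container", {
  set.seed(9)
  u <- array(rnorm(6 * 5 * 2), c(6, 5, 2))
  path <- tempfile(fileext = ".field")
  write_field(u, path)
  expect_equal(read_field(path), u, tolerance = 1e-12)
})
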