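test_that("frame 1 is a byte-identical passthrough and shapes are preserved", {
  ph <- tiny_phantom(seed = 1)
  model <- build_rgb_registrar(48, 48, seed = 1)
  reg <- suppressWarnings(register_sequence(model, ph))
  expect_identical(reg$frames[[1]], ph$frames[[1]])
  expect_length(reg$frames, 5)
  expect_length(reg$fields, 5)
  expect_equal(reg$fields[[1]][[1]], zero_field(48, 48))
  expect_length(reg$fields[[2]], 3)  # one field per channel in rgb mode
})

test_that("an untrained model returns a near-identity registration with a warning", {
  ph <- tiny_phantom(seed = 2)
  model <- build_rgb_registrar(48, 48, seed = 3)
  expect_warning(reg <- register_sequence(model, ph), "near zero")
  for (t in 2:5)
    expect_equal(reg$frames[[t]], ph$frames[[t]], tolerance = 1e-3)
})

test_that("registration validates resolution and model class", {
  ph <- tiny_phantom(seed = 3)
  model <- build_rgb_registrar(32, 32, seed = 1)
  expect_error(register_sequence(model, ph), "trained at")
  b <- build_branch(48, 48, seed = 1)
  expect_error(register_sequence(b, ph, mode = "rgb"), "three branches")
})

test_that("altering one branch changes only that colour plane", {
  ph <- tiny_phantom(seed = 4)
  model <- build_rgb_registrar(48, 48, seed = 5)
  reg0 <- suppressWarnings(register_sequence(model, ph))
  model$b$layers$head$b <- c(1.5, -0.8)  # perturb only the blue branch
  reg1 <- suppressWarnings(register_sequence(model, ph))
  for (t in 2:5) {
    expect_identical(reg1$frames[[t]][, , 1], reg0$frames[[t]][, , 1])
    expect_identical(reg1$frames[[t]][, , 2], reg0$frames[[t]][, , 2])
    expect_false(identical(reg1$frames[[t]][, , 3], reg0$frames[[t]][, , 3]))
  }
})

test_that("single-channel registration applies one field to all planes", {
  ph <- tiny_phantom(seed = 5)
  b <- build_branch(48, 48, seed = 2)
  b$layers$head$b <- c(2, 0)  # constant 2 px row shift
  reg <- register_sequence(b, ph, mode = "grayscale")
  expect_length(reg$fields[[2]], 1)
  for (ch in 1:3)
    expect_equal(reg$frames[[2]][, , ch],
                 clip01(warp(ph$frames[[2]][, , ch], reg$fields[[2]][[1]])),
                 tolerance = 1e-12)
})

test_that("mask transport is nearest-neighbour and matches a per-pixel oracle", {
  mask <- random_mask(12, 12, seed = 8)
  # zero field: unchanged
  expect_identical(transport_mask(mask, zero_field(12, 12)), mask)
  # integer translation: interior equals the shifted mask
  u <- zero_field(12, 12)
  u[, , 1] <- 3
  shifted <- transport_mask(mask, u)
  expect_equal(shifted[1:9, ], mask[4:12, ])
  # arbitrary field vs brute-force nearest-neighbour enumeration
  set.seed(9)
  uf <- array(rnorm(12 * 12 * 2, 0, 1.5), c(12, 12, 2))
  got <- transport_mask(mask, uf)
  expect_true(all(got %in% c(0, 1)))
  for (r in 1:12) {
    for (cc in 1:12) {
      sr <- min(max(round((r - 1) + uf[r, cc, 1]), 0), 11) + 1
      sc <- min(max(round((cc - 1) + uf[r, cc, 2]), 0), 11) + 1
      expect_equal(got[r, cc], mask[sr, sc])
    }
  }
  # channel policy picks the requested field from a per-channel list
  fields <- list(zero_field(12, 12), u, zero_field(12, 12))
  expect_identical(transport_mask(mask, fields, channel_policy = "green"), shifted)
  expect_identical(transport_mask(mask, fields, channel_policy = "red"), mask)
})

test_that("a field-biased registrar improves alignment of a shifted phantom", {
  # direct functional check without training: feed the known inverse rigid
  # field through the mask-transport path and verify the Dice gain
  ph <- tiny_phantom(seed = 10, noise_sigma = 0)
  tr <- ph$truth$transforms
  d_before <- d_after <- c()
  for (t in 2:5) {
    u <- rigid_field(tr$rotation[t], tr$dy[t], tr$dx[t], 48, 48)
    d_before <- c(d_before, dice(ph$truth$masks[[t]], ph$truth$masks[[1]]))
    d_after <- c(d_after, dice(transport_mask(ph$truth$masks[[t]], u),
                               ph$truth$masks[[1]]))
  }
  expect_gt(mean(d_after), 0.97)
  expect_gt(mean(d_after), mean(d_before))
})
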