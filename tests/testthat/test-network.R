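test_that("default widths build a 4+4 stage network with a 2-channel head", {
  b <- build_branch(32, 32, seed = 1)
  expect_s3_class(b, "branch_network")
  expect_setequal(names(b$layers),
                  c(paste0("enc", 1:4), paste0("dec", 1:4), "head"))
  expect_equal(dim(b$layers$enc1$w), c(3, 3, 2, 16))
  expect_equal(dim(b$layers$head$w)[4], 2)
  expect_equal(b$widths, c(16L, 32L, 32L, 32L, 32L, 32L, 32L, 16L))
  expect_error(build_branch(30, 32), "divisible")
  expect_error(build_branch(32, 32, widths = c(16, 32, 16)), "evenly")
})

test_that("a fresh branch predicts a near-zero field (identity warp start)", {
  b <- build_branch(32, 32, seed = 2)
  set.seed(3)
  f <- matrix(runif(1024), 32, 32)
  m <- matrix(runif(1024), 32, 32)
  u <- predict_field(b, f, m)
  expect_equal(dim(u), c(32L, 32L, 2L))
  expect_lt(max(abs(u)), 0.1)
  expect_equal(warp(m, u), m, tolerance = 1e-3)
})

test_that("construction and prediction are deterministic", {
  b1 <- build_branch(32, 32, seed = 42)
  b2 <- build_branch(32, 32, seed = 42)
  expect_identical(b1$layers, b2$layers)
  b3 <- build_branch(32, 32, seed = 43)
  expect_false(identical(b1$layers$enc1$w, b3$layers$enc1$w))
  set.seed(4)
  f <- matrix(runif(1024), 32, 32)
  m <- matrix(runif(1024), 32, 32)
  expect_identical(predict_field(b1, f, m), predict_field(b2, f, m))
})

test_that("rgb registrar holds three architecture-identical, parameter-independent branches", {
  reg <- build_rgb_registrar(32, 32, seed = 1)
  expect_s3_class(reg, "rgb_registrar")
  expect_named(unclass(reg), c("r", "g", "b"))
  expect_identical(reg$r$widths, reg$g$widths)
  expect_false(identical(reg$r$layers$enc1$w, reg$g$layers$enc1$w))
})

test_that("field resolution equals input resolution across sizes", {
  for (hw in list(c(16, 32), c(48, 16))) {
    b <- build_branch(hw[1], hw[2], seed = 1)
    u <- predict_field(b, matrix(0.5, hw[1], hw[2]), matrix(0.4, hw[1], hw[2]))
    expect_equal(dim(u), c(hw[1], hw[2], 2L))
  }
  b <- build_branch(32, 32, seed = 1)
  expect_error(predict_field(b, matrix(0, 16, 16), matrix(0, 16, 16)), "built for")
})

test_that("autodiff gradient of the total loss matches finite differences", {
  set.seed(11)
  H <- 16
  f <- matrix(runif(H * H), H, H)
  m <- matrix(runif(H * H), H, H)
  b <- build_branch(H, H, seed = 7)
  # use a non-degenerate head so the field is away from the integer grid,
  # where bilinear sampling is smooth
  b$layers$head$w[] <- rnorm(length(b$layers$head$w), 0, 0.05)
  b$layers$head$b <- c(0.3, 0.3)
  cfg <- loss_config(lambda_smooth = 1)
  loss_of <- function(br) {
    u <- colporeg:::branch_forward(br, array(c(f, m), c(H, H, 2)))
    similarity_loss(f, warp(m, u), cfg) + cfg$lambda_smooth * smoothness_loss(u)
  }
  cache <- colporeg:::branch_forward(b, array(c(f, m), c(H, H, 2)), want_cache = TRUE)
  u <- cache$field
  wm <- warp(m, u)
  gimg <- colporeg:::similarity_grad(f, wm, cfg)
  dim(gimg) <- c(H, H)
  gfield <- colporeg:::warp_bilinear_bw_cpp(m, u, gimg)$gfield +
    colporeg:::smoothness_grad(u)
  grads <- colporeg:::branch_backward(b, cache, gfield)
  h <- 1e-5
  for (nm in c("enc1", "enc4", "dec2", "dec4", "head")) {
    for (i in sample(length(b$layers[[nm]]$w), 3)) {
      bp <- b; bp$layers[[nm]]$w[i] <- bp$layers[[nm]]$w[i] + h
      bm <- b; bm$layers[[nm]]$w[i] <- bm$layers[[nm]]$w[i] - h
      num <- (loss_of(bp) - loss_of(bm)) / (2 * h)
      ana <- grads[[nm]]$w[i]
      expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-3)
    }
    # bias gradient too
    bp <- b; bp$layers[[nm]]$b[1] <- bp$layers[[nm]]$b[1] + h
    bm <- b; bm$layers[[nm]]$b[1] <- bm$layers[[nm]]$b[1] - h
    num <- (loss_of(bp) - loss_of(bm)) / (2 * h)
    expect_lt(abs(num - grads[[nm]]$b[1]) / max(abs(num), 1e-8), 1e-3)
  }
})

test_that("direct and im2col convolution kernels agree", {
  set.seed(17)
  for (shape in list(c(16, 16, 4, 8, 1), c(15, 13, 3, 5, 2), c(8, 8, 6, 2, 1))) {
    H <- shape[1]; W <- shape[2]; Cin <- shape[3]; Cout <- shape[4]
    s <- shape[5]
    x <- array(rnorm(H * W * Cin), c(H, W, Cin))
    w <- array(rnorm(9 * Cin * Cout, 0, 0.2), c(3, 3, Cin, Cout))
    b <- rnorm(Cout)
    y1 <- colporeg:::conv2d_fw_cpp(x, w, b, s, 1L)
    y2 <- colporeg:::conv2d_dfw_cpp(x, w, b, s, 1L)
    expect_equal(y1, y2, tolerance = 1e-12)
    gy <- array(rnorm(length(y1)), dim(y1))
    b1 <- colporeg:::conv2d_bw_cpp(x, w, gy, s, 1L)
    b2 <- colporeg:::conv2d_dbw_cpp(x, w, gy, s, 1L, TRUE)
    expect_equal(b1$gx, b2$gx, tolerance = 1e-12)
    expect_equal(b1$gw, b2$gw, tolerance = 1e-12)
    expect_equal(b1$gb, b2$gb, tolerance = 1e-12)
  }
})

test_that("checkpoints round-trip with a JSON architecture sidecar", {
  b <- build_branch(16, 16, seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(b, path)
  expect_true(file.exists(paste0(path, ".json")))
  b2 <- load_checkpoint(path)
  expect_identical(b2$layers, b$layers)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$widths, b$widths)
  expect_equal(side$kernel_size, 3)
})
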