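test_that("mse similarity matches closed forms", {
  a <- matrix(runif(36), 6, 6)
  expect_equal(similarity_loss(a, a), 0)
  expect_equal(similarity_loss(matrix(0, 4, 4), matrix(0.5, 4, 4)), 0.25)
  f <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  m <- matrix(c(0.1, 0.9, 0.5, 0.45), 2, 2)
  expect_equal(similarity_loss(f, m), mean((f - m)^2))
})

test_that("lncc matches a window-by-window brute-force oracle", {
  set.seed(21)
  f <- matrix(runif(64), 8, 8)
  m <- 0.3 * f + matrix(runif(64, 0, 0.5), 8, 8)
  n <- 5
  cfg <- loss_config(similarity = "lncc", lncc_window = n)
  # oracle: enumerate every fully contained window, epsilon-stabilized as in
  # the implementation contract
  eps <- 1e-5
  vals <- c()
  for (r in 1:(8 - n + 1)) {
    for (cc in 1:(8 - n + 1)) {
      fw <- as.numeric(f[r:(r + n - 1), cc:(cc + n - 1)])
      mw <- as.numeric(m[r:(r + n - 1), cc:(cc + n - 1)])
      A <- sum(fw * mw) - sum(fw) * sum(mw) / n^2
      B <- sum(fw^2) - sum(fw)^2 / n^2
      C <- sum(mw^2) - sum(mw)^2 / n^2
      vals <- c(vals, A / sqrt(B * C + eps))
    }
  }
  expect_equal(similarity_loss(f, m, cfg), -mean(vals), tolerance = 1e-10)
  # perfectly matched images approach -1
  expect_lt(similarity_loss(f, f, cfg), -0.99)
})

test_that("lncc on constant windows is epsilon-stabilized, not NaN", {
  f <- matrix(0.5, 8, 8)
  m <- matrix(runif(64), 8, 8)
  cfg <- loss_config(similarity = "lncc", lncc_window = 5)
  v <- similarity_loss(f, m, cfg)
  expect_true(is.finite(v))
})

test_that("smoothness loss has closed forms and k^2 homogeneity", {
  # any constant field (global translation) costs nothing
  u <- zero_field(6, 6)
  u[, , 1] <- 3.2
  u[, , 2] <- -1.7
  expect_equal(smoothness_loss(u), 0)
  # unit horizontal shear on a 4x4 field: brute-force finite differences
  us <- zero_field(4, 4)
  us[, , 2] <- matrix(rep(0:3, each = 4), 4, 4)
  acc <- c()
  for (comp in 1:2) {
    for (r in 1:3) for (cc in 1:4) acc <- c(acc, (us[r + 1, cc, comp] - us[r, cc, comp])^2)
    for (r in 1:4) for (cc in 1:3) acc <- c(acc, (us[r, cc + 1, comp] - us[r, cc, comp])^2)
  }
  expect_equal(smoothness_loss(us), mean(acc))
  # homogeneity
  set.seed(5)
  ur <- array(rnorm(50), c(5, 5, 2))
  expect_equal(smoothness_loss(3 * ur), 9 * smoothness_loss(ur), tolerance = 1e-12)
})

test_that("smoothness gradient matches finite differences", {
  set.seed(6)
  u <- array(rnorm(32), c(4, 4, 2))
  g <- colporeg:::smoothness_grad(u)
  h <- 1e-6
  for (i in sample(32, 6)) {
    up <- u; up[i] <- up[i] + h
    um <- u; um[i] <- um[i] - h
    expect_equal(g[i], (smoothness_loss(up) - smoothness_loss(um)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("total loss aggregates channels and matches an unrolled oracle", {
  set.seed(8)
  H <- 4; W <- 4
  pairs <- lapply(1:3, function(i)
    list(fixed = matrix(runif(H * W), H, W), moving = matrix(runif(H * W), H, W)))
  fields <- lapply(1:3, function(i) array(rnorm(H * W * 2, 0, 0.3), c(H, W, 2)))
  cfg <- loss_config(lambda_smooth = 0.7)
  # unrolled scalar computation
  tot <- 0
  for (i in 1:3) {
    wm <- warp(pairs[[i]]$moving, fields[[i]])
    tot <- tot + mean((pairs[[i]]$fixed - wm)^2) + 0.7 * smoothness_loss(fields[[i]])
  }
  expect_equal(total_loss(pairs, fields, cfg), tot, tolerance = 1e-12)
  # identical frames + zero fields = global minimum 0 under mse
  id_pairs <- lapply(1:3, function(i) list(fixed = pairs[[i]]$fixed,
                                           moving = pairs[[i]]$fixed))
  zf <- replicate(3, zero_field(H, W), simplify = FALSE)
  expect_equal(total_loss(id_pairs, zf, cfg), 0)
  # lambda 0 reduces to similarity alone
  cfg0 <- loss_config(lambda_smooth = 0)
  sim_only <- sum(sapply(1:3, function(i)
    similarity_loss(pairs[[i]]$fixed, warp(pairs[[i]]$moving, fields[[i]]), cfg0)))
  expect_equal(total_loss(pairs, fields, cfg0), sim_only)
  # single-channel aggregation reproduces the per-branch loss
  one <- total_loss(pairs[1], fields[1], cfg)
  expect_equal(one, similarity_loss(pairs[[1]]$fixed,
                                    warp(pairs[[1]]$moving, fields[[1]]), cfg) +
                 0.7 * smoothness_loss(fields[[1]]))
})

test_that("loss config rejects invalid settings", {
  expect_error(loss_config(lncc_window = 4), "odd")
  expect_error(loss_config(lambda_smooth = -1), ">= 0")
})
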