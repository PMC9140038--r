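#' Loss configuration
#'
#' @param similarity `"mse"` (mean squared intensity difference, the default)
#'   or `"lncc"` (negated mean local normalized cross-correlation).
#' @param lncc_window odd window edge length in pixels for `"lncc"`
#'   (default 9).
#' @param lambda_smooth non-negative weight on the displacement-smoothness
#'   (local spatial variation) term. Default 1.0.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(similarity = c("mse", "lncc"), lncc_window = 9L,
                        lambda_smooth = 1.0) {
  similarity <- match.arg(similarity)
  lncc_window <- as.integer(lncc_window)
  if (lncc_window < 3L || lncc_window %% 2L == 0L)
    stop("`lncc_window` must be odd and >= 3", call. = FALSE)
  if (lambda_smooth < 0) stop("`lambda_smooth` must be >= 0", call. = FALSE)
  structure(list(similarity = similarity, lncc_window = lncc_window,
                 lambda_smooth = lambda_smooth), class = "loss_config")
}

#' Similarity loss between a fixed and a warped moving channel
#'
#' With `similarity = "mse"`, the mean over pixels of the squared intensity
#' difference; zero iff the images match exactly. With `"lncc"`, the negated
#' mean of the local Pearson correlation computed over every fully contained
#' `w x w` window (epsilon-stabilized denominator); -1 iff perfectly
#' correlated in every window.
#'
#' @param fixed,warped numeric `H x W` matrices.
#' @param config a [loss_config()].
#' @return scalar loss.
#' @export
similarity_loss <- function(fixed, warped, config = loss_config()) {
  assert_same_hw(fixed, warped, "fixed and warped")
  if (config$similarity == "mse") {
    mean((fixed - warped)^2)
  } else {
    -mean(lncc_map(fixed, warped, config$lncc_window)$corr)
  }
}

# dL/dwarped for the similarity term.
similarity_grad <- function(fixed, warped, config) {
  if (config$similarity == "mse")
    return(2 * (warped - fixed) / length(fixed))
  lncc_grad(fixed, warped, config$lncc_window)
}

# Local correlation over all fully contained n x n windows, via box sums
# computed with a valid ones-kernel convolution. Returns the per-window
# statistics needed for both the loss and its gradient.
lncc_map <- function(f, m, n, eps = 1e-5) {
  H <- nrow(f)
  W <- ncol(f)
  if (H < n || W < n)
    stop(sprintf("lncc window (%d) exceeds image size %dx%d", n, H, W),
         call. = FALSE)
  ones <- array(1, c(n, n, 1, 1))
  box <- function(x) conv2d_fw_cpp(array(x, c(H, W, 1)), ones, 0, 1L, 0L)[, , 1]
  n2 <- n * n
  Sf <- box(f); Sm <- box(m)
  Sff <- box(f * f); Smm <- box(m * m); Sfm <- box(f * m)
  A <- Sfm - Sf * Sm / n2
  B <- Sff - Sf^2 / n2
  C <- Smm - Sm^2 / n2
  D <- sqrt(pmax(B * C, 0) + eps)
  list(corr = A / D, A = A, B = B, C = C, D = D, Sf = Sf, Sm = Sm, n = n)
}

# Gradient of -mean(corr) w.r.t. the moving (warped) image. For window p and
# pixel q inside it: dcorr_p/dm_q = (f_q - muf_p)/D_p - A_p B_p (m_q - mum_p)/D_p^3.
lncc_grad <- function(f, m, n, eps = 1e-5) {
  H <- nrow(f)
  W <- ncol(f)
  st <- lncc_map(f, m, n, eps)
  n2 <- n * n
  N <- length(st$A)
  ones <- array(1, c(n, n, 1, 1))
  # adjoint of the valid box sum: scatter per-window values back over pixels
  unbox <- function(P) {
    g <- conv2d_bw_cpp(array(0, c(H, W, 1)), ones,
                       array(P, c(dim(st$A), 1)), 1L, 0L)$gx[, , 1]
    g
  }
  invD <- 1 / st$D
  ABD3 <- st$A * st$B / st$D^3
  muf <- st$Sf / n2
  mum <- st$Sm / n2
  term <- f * unbox(invD) - unbox(muf * invD) -
    m * unbox(ABD3) + unbox(mum * ABD3)
  -(term) / N
}

#' Displacement-smoothness (local spatial variation) loss
#'
#' The mean of the squared forward-difference spatial gradients of the
#' displacement field, over both components and both directions. Zero iff the
#' field is spatially constant (any global translation is free); scaling the
#' field by `k` scales the loss by `k^2`.
#'
#' @param field `H x W x 2` displacement field.
#' @return scalar loss `>= 0`.
#' @export
smoothness_loss <- function(field) {
  check_field(field)
  H <- dim(field)[1]
  W <- dim(field)[2]
  dr <- field[-1, , , drop = FALSE] - field[-H, , , drop = FALSE]
  dc <- field[, -1, , drop = FALSE] - field[, -W, , drop = FALSE]
  (sum(dr^2) + sum(dc^2)) / (length(dr) + length(dc))
}

smoothness_grad <- function(field) {
  H <- dim(field)[1]
  W <- dim(field)[2]
  dr <- field[-1, , , drop = FALSE] - field[-H, , , drop = FALSE]
  dc <- field[, -1, , drop = FALSE] - field[, -W, , drop = FALSE]
  denom <- length(dr) + length(dc)
  g <- array(0, dim(field))
  g[-1, , ] <- g[-1, , ] + 2 * dr
  g[-H, , ] <- g[-H, , ] - 2 * dr
  g[, -1, ] <- g[, -1, ] + 2 * dc
  g[, -W, ] <- g[, -W, ] - 2 * dc
  g / denom
}

#' Aggregated training objective over channel branches
#'
#' For each channel `c`, warps the moving channel by its field and accumulates
#' `similarity_loss(fixed_c, warp(moving_c, u_c)) + lambda_smooth *
#' smoothness_loss(u_c)`. In RGB mode there are exactly three (pair, field)
#' entries; single-channel training passes one.
#'
#' @param pairs list of channel pairs, each `list(fixed =, moving =)`.
#' @param fields list of displacement fields, one per pair.
#' @param config a [loss_config()].
#' @return scalar total loss.
#' @export
total_loss <- function(pairs, fields, config = loss_config()) {
  if (!is.list(pairs) || !is.list(fields) || length(pairs) != length(fields))
    stop("`pairs` and `fields` must be lists of equal length", call. = FALSE)
  if (length(pairs) == 0L) stop("at least one channel is required", call. = FALSE)
  tot <- 0
  for (i in seq_along(pairs)) {
    u <- fields[[i]]
    wm <- warp(pairs[[i]]$moving, u)
    tot <- tot + similarity_loss(pairs[[i]]$fixed, wm, config) +
      config$lambda_smooth * smoothness_loss(u)
  }
  tot
}
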