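#' Build one single-channel registration branch
#'
#' Constructs an encoder-decoder CNN `g` that maps a (fixed, moving) channel
#' pair to a dense 2-channel displacement field at input resolution. The
#' default channel widths `[16, 32, 32, 32, 32, 32, 32, 16]` split into a
#' 4-stage encoder (each a stride-2 3x3 convolution) and a 4-stage decoder
#' (each a nearest x2 upsampling, a skip concatenation from the matching
#' encoder resolution, and a 3x3 convolution), all with Leaky-ReLU
#' activations (negative slope 0.2). A final linear 3x3 convolution emits the
#' 2-channel field. The final layer is initialized near zero (weight sd 1e-5,
#' zero bias) so a freshly built branch predicts the identity warp.
#'
#' @param height,width input resolution; both must be divisible by
#'   `2^(number of encoder stages)` (16 for the default widths).
#' @param widths integer vector of channel widths, split evenly into encoder
#'   and decoder halves.
#' @param seed integer seed for the (He-scaled) weight initialization; equal
#'   seeds give identical parameters.
#' @return an object of class `branch_network`.
#' @export
build_branch <- function(height, width, widths = c(16, 32, 32, 32, 32, 32, 32, 16),
                         seed = 1L) {
  n <- length(widths)
  if (n < 2L || n %% 2L != 0L)
    stop("`widths` must split evenly into encoder and decoder halves", call. = FALSE)
  n_enc <- n %/% 2L
  div <- 2L^n_enc
  if (height %% div != 0L || width %% div != 0L)
    stop(sprintf("height and width must be divisible by %d", div), call. = FALSE)
  enc_w <- widths[seq_len(n_enc)]
  dec_w <- widths[n_enc + seq_len(n_enc)]
  with_seed(seed, {
    layers <- list()
    cin <- 2L
    for (i in seq_len(n_enc)) {
      layers[[paste0("enc", i)]] <- init_conv(cin, enc_w[i])
      cin <- enc_w[i]
    }
    # decoder stage i consumes upsampled previous output plus the skip from
    # encoder stage (n_enc - i); the last skip is the 2-channel input itself.
    skip_ch <- c(rev(enc_w[-n_enc]), 2L)
    for (i in seq_len(n_enc)) {
      layers[[paste0("dec", i)]] <- init_conv(cin + skip_ch[i], dec_w[i])
      cin <- dec_w[i]
    }
    layers[["head"]] <- init_conv(cin, 2L, sd = 1e-5)
    structure(list(
      layers = layers, widths = as.integer(widths), n_enc = n_enc,
      kernel_size = 3L, activation_slope = 0.2,
      height = as.integer(height), width = as.integer(width),
      seed = as.integer(seed)
    ), class = "branch_network")
  })
}

init_conv <- function(cin, cout, k = 3L, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (k * k * cin))  # He initialization
  list(w = array(rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

#' Build an RGB registrar of three independent branches
#'
#' The three branches share the same architecture but hold independent
#' parameters; branch `r`/`g`/`b` registers the corresponding colour plane.
#'
#' @inheritParams build_branch
#' @return an object of class `rgb_registrar` with elements `r`, `g`, `b`.
#' @export
build_rgb_registrar <- function(height, width,
                                widths = c(16, 32, 32, 32, 32, 32, 32, 16),
                                seed = 1L) {
  branches <- lapply(1:3, function(i)
    build_branch(height, width, widths, seed = seed + i - 1L))
  names(branches) <- c("r", "g", "b")
  structure(branches, class = "rgb_registrar",
            height = as.integer(height), width = as.integer(width))
}

# Forward pass; returns the field and (optionally) the cache needed for the
# backward pass.
branch_forward <- function(branch, x0, want_cache = FALSE) {
  n_enc <- branch$n_enc
  slope <- branch$activation_slope
  acts <- list(x0)   # acts[[i+1]] = activated output of encoder stage i
  decs <- list()     # activated decoder outputs
  As <- list()       # cached im2col matrices, reused by the backward pass
  conv <- function(x, layer, stride, nm) {
    if (!want_cache)
      return(conv2d_fw_cpp(x, layer$w, layer$b, stride, 1L))
    fw <- conv2d_fwA_cpp(x, layer$w, layer$b, stride, 1L)
    As[[nm]] <<- fw$A
    fw$y
  }
  x <- x0
  for (i in seq_len(n_enc)) {
    nm <- paste0("enc", i)
    x <- lrelu_fw_cpp(conv(x, branch$layers[[nm]], 2L, nm), slope)
    acts[[i + 1]] <- x
  }
  for (i in seq_len(n_enc)) {
    nm <- paste0("dec", i)
    din <- concat_ch_cpp(upsample2_fw_cpp(x), acts[[n_enc - i + 1]])
    x <- lrelu_fw_cpp(conv(din, branch$layers[[nm]], 1L, nm), slope)
    decs[[nm]] <- x
  }
  field <- conv(x, branch$layers$head, 1L, "head")
  if (!want_cache) return(field)
  list(field = field, acts = acts, decs = decs, As = As)
}

# Backward pass: gradient of a scalar loss w.r.t. all branch parameters,
# given dL/dfield. Returns a list of per-layer list(w, b) gradients.
branch_backward <- function(branch, cache, gfield) {
  n_enc <- branch$n_enc
  slope <- branch$activation_slope
  grads <- list()
  hdim <- dim(cache$decs[[paste0("dec", n_enc)]])
  bw <- conv2d_bwA_cpp(cache$As$head, branch$layers$head$w, gfield,
                       hdim[1], hdim[2], 1L, 1L, TRUE)
  grads$head <- list(w = bw$gw, b = bw$gb)
  g <- bw$gx
  gskips <- vector("list", n_enc + 1)  # gradient flowing into acts[[j]]
  for (i in rev(seq_len(n_enc))) {
    nm <- paste0("dec", i)
    gz <- lrelu_bw_cpp(cache$decs[[nm]], g, slope)
    d <- dim(gz)
    bw <- conv2d_bwA_cpp(cache$As[[nm]], branch$layers[[nm]]$w, gz,
                         d[1], d[2], 1L, 1L, TRUE)
    grads[[nm]] <- list(w = bw$gw, b = bw$gb)
    gin <- bw$gx
    cup <- dim(gin)[3] - dim(cache$acts[[n_enc - i + 1]])[3]
    gup <- gin[, , seq_len(cup), drop = FALSE]
    gsk <- gin[, , cup + seq_len(dim(gin)[3] - cup), drop = FALSE]
    j <- n_enc - i + 1
    gskips[[j]] <- if (is.null(gskips[[j]])) gsk else gskips[[j]] + gsk
    g <- upsample2_bw_cpp(gup)
  }
  # g now flows into the output of the last encoder stage; add skip gradients
  # while walking back through the encoder. The first encoder layer's input
  # is the data pair, so its input gradient is never materialized.
  for (i in rev(seq_len(n_enc))) {
    if (!is.null(gskips[[i + 1]])) g <- g + gskips[[i + 1]]
    nm <- paste0("enc", i)
    gz <- lrelu_bw_cpp(cache$acts[[i + 1]], g, slope)
    d <- dim(cache$acts[[i]])
    bw <- conv2d_bwA_cpp(cache$As[[nm]], branch$layers[[nm]]$w, gz,
                         d[1], d[2], 2L, 1L, i > 1L)
    grads[[nm]] <- list(w = bw$gw, b = bw$gb)
    if (i > 1L) g <- bw$gx
  }
  grads
}

#' Predict the displacement field for a (fixed, moving) channel pair
#'
#' Runs one branch forward on the two-channel stack `(fixed, moving)` and
#' returns the dense displacement field, in pixels, at input resolution. The
#' result is deterministic given the parameters and inputs.
#'
#' @param branch a [build_branch()] network.
#' @param fixed,moving numeric `H x W` matrices in `[0, 1]`; dimensions must
#'   match the branch's build resolution.
#' @return `H x W x 2` displacement field (dy, dx).
#' @export
predict_field <- function(branch, fixed, moving) {
  stopifnot(inherits(branch, "branch_network"))
  if (!identical(dim(fixed), dim(moving)))
    stop("fixed and moving must have identical dimensions", call. = FALSE)
  if (!identical(as.integer(dim(fixed)), c(branch$height, branch$width)))
    stop(sprintf("input is %s but branch was built for %dx%d",
                 paste(dim(fixed), collapse = "x"), branch$height, branch$width),
         call. = FALSE)
  x0 <- array(c(fixed, moving), c(branch$height, branch$width, 2))
  branch_forward(branch, x0)
}

#' Save / load network parameters
#'
#' Checkpoints are written with R's native serialization (`saveRDS`), next to
#' a JSON sidecar recording the architecture (widths, resolution, kernel
#' size, activation slope) for reproducibility.
#'
#' @param model a `branch_network` or `rgb_registrar`.
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `load_checkpoint` returns the model; `save_checkpoint` its path,
#'   invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("branch_network", "rgb_registrar")))
  saveRDS(model, path)
  b <- if (inherits(model, "rgb_registrar")) model[[1]] else model
  jsonlite::write_json(list(
    class = class(model)[1], widths = b$widths, kernel_size = b$kernel_size,
    activation_slope = b$activation_slope, height = b$height, width = b$width
  ), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, c("branch_network", "rgb_registrar")))
  model
}

#' @export
print.branch_network <- function(x, ...) {
  cat(sprintf("branch_network: %dx%d input, widths [%s], %d parameters\n",
              x$height, x$width, paste(x$widths, collapse = ", "),
              n_parameters(x)))
  invisible(x)
}

#' @export
print.rgb_registrar <- function(x, ...) {
  cat(sprintf("rgb_registrar: three branches at %dx%d, %d parameters each\n",
              attr(x, "height"), attr(x, "width"), n_parameters(x$r)))
  invisible(x)
}

n_parameters <- function(branch) {
  sum(vapply(branch$layers, function(l) length(l$w) + length(l$b), numeric(1)))
}
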