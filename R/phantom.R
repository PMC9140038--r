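#' Configuration of the acetowhitening phantom generator
#'
#' The phantom emulates a colposcopy time sequence: a roughly elliptical
#' bright cervix on a darker background, with a darker interior os region,
#' whose epithelium brightens monotonically over the sequence
#' (acetowhitening), while the whole scene is misaligned frame-to-frame by a
#' random rigid transform and perturbed by illumination jitter and Gaussian
#' noise. Ground-truth masks and transforms are recorded, so registration
#' quality can be scored exactly.
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' tests: 64 x 64 frames, 17 frames per sequence, translations up to 6 px and
#' rotations up to 4 degrees.
#'
#' @param height,width frame dimensions in pixels.
#' @param n_frames number of frames in the sequence (>= 2; default 17, the
#'   length of a routine dynamic colposcopy acquisition).
#' @param cervix_center (row, col) centre of the cervix ellipse, 0-based
#'   pixels; defaults to the image centre.
#' @param cervix_axes (a, b) semi-axes of the cervix ellipse in pixels
#'   (rows, cols); defaults scale with the frame size (3/8 of the height,
#'   5/16 of the width - 24 x 20 px at the default 64 x 64).
#' @param os_axes (a, b) semi-axes of the os ellipse; must fit strictly
#'   inside the cervix ellipse. Defaults scale with the frame size.
#' @param whitening_rate per-frame brightening coefficient in `[0, 1]`; 0
#'   disables acetowhitening.
#' @param max_translation maximum absolute per-frame translation in pixels.
#' @param max_rotation maximum absolute per-frame rotation in degrees.
#' @param illumination_jitter maximum fractional per-channel gain jitter.
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   `[0, 1]` intensity scale.
#' @param elastic_sigma amplitude (pixels) of an optional smooth elastic
#'   perturbation added on top of the rigid motion; 0 (default) keeps the
#'   misalignment purely rigid so overlap oracles are exact.
#' @param seed integer seed; equal configurations with equal seeds produce
#'   bit-identical sequences.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(height = 64, width = 64, n_frames = 17,
                           cervix_center = NULL,
                           cervix_axes = NULL,
                           os_axes = NULL,
                           whitening_rate = 0.15,
                           max_translation = 6,
                           max_rotation = 4,
                           illumination_jitter = 0.05,
                           noise_sigma = 0.01,
                           elastic_sigma = 0,
                           seed = 1L) {
  if (is.null(cervix_center)) cervix_center <- c((height - 1) / 2, (width - 1) / 2)
  if (is.null(cervix_axes)) cervix_axes <- c(round(height * 3 / 8), round(width * 5 / 16))
  if (is.null(os_axes)) os_axes <- pmax(c(round(height * 3 / 32), round(width * 5 / 64)), 2)
  cfg <- structure(list(
    height = as.integer(height), width = as.integer(width),
    n_frames = as.integer(n_frames),
    cervix_center = as.numeric(cervix_center),
    cervix_axes = as.numeric(cervix_axes), os_axes = as.numeric(os_axes),
    whitening_rate = whitening_rate,
    max_translation = max_translation, max_rotation = max_rotation,
    illumination_jitter = illumination_jitter, noise_sigma = noise_sigma,
    elastic_sigma = elastic_sigma,
    seed = as.integer(seed)
  ), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_frames < 2L)
    stop("phantom: n_frames must be >= 2", call. = FALSE)
  if (any(cfg$os_axes >= cfg$cervix_axes))
    stop("phantom: os ellipse must be strictly contained in the cervix ellipse",
         call. = FALSE)
  if (any(c(cfg$cervix_axes, cfg$os_axes) <= 0))
    stop("phantom: ellipse axes must be positive", call. = FALSE)
  margin <- cfg$max_translation + 1
  if (cfg$cervix_center[1] - cfg$cervix_axes[1] - margin < 0 ||
      cfg$cervix_center[1] + cfg$cervix_axes[1] + margin > cfg$height - 1 ||
      cfg$cervix_center[2] - cfg$cervix_axes[2] - margin < 0 ||
      cfg$cervix_center[2] + cfg$cervix_axes[2] + margin > cfg$width - 1)
    stop("phantom: cervix geometry (plus max_translation) exceeds image bounds",
         call. = FALSE)
  if (cfg$whitening_rate < 0 || cfg$whitening_rate > 1)
    stop("phantom: whitening_rate must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_sigma < 0 || cfg$illumination_jitter < 0 ||
      cfg$max_translation < 0 || cfg$max_rotation < 0 || cfg$elastic_sigma < 0)
    stop("phantom: noise/jitter/motion parameters must be non-negative",
         call. = FALSE)
  invisible(cfg)
}

#' Acetowhitening brightness multiplier for frame t
#'
#' A saturating-exponential profile
#' `w(t) = 1 + A * (1 - exp(-rate * (t - 1)))` with fixed amplitude
#' `A = 0.3`: the cervix epithelium brightens quickly after acid application
#' and then plateaus. The profile is 1 at `t = 1`, monotone non-decreasing in
#' `t`, identically 1 when `whitening_rate = 0`, and bounded so that phantom
#' intensities (base cervix colour times multiplier) never exceed 1.
#'
#' @param t frame index, `1 <= t <= n_frames`.
#' @param config a [phantom_config()].
#' @return scalar multiplier >= 1.
#' @export
whitening_profile <- function(t, config) {
  if (any(t < 1) || any(t > config$n_frames))
    stop(sprintf("frame index out of range 1..%d", config$n_frames), call. = FALSE)
  1 + 0.3 * (1 - exp(-config$whitening_rate * (t - 1)))
}

# Base scene colours (R, G, B): background tissue, cervix epithelium, os.
.phantom_colors <- list(
  bg     = c(0.32, 0.16, 0.18),
  cervix = c(0.72, 0.42, 0.42),
  os     = c(0.42, 0.13, 0.16)
)

# Continuous scene function evaluated at arbitrary (row, col) coordinates in
# frame-1 geometry. `sy`, `sx` are matrices of sampling coordinates. Returns
# an H x W x 3 array. Edges are smoothed over ~1.5 px and the cervix carries
# a mild radial shading so the interior is not gradient-free.
render_scene <- function(sy, sx, cfg, t) {
  smoothstep <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    x * x * (3 - 2 * x)
  }
  dy <- sy - cfg$cervix_center[1]
  dx <- sx - cfg$cervix_center[2]
  rho_c <- sqrt((dy / cfg$cervix_axes[1])^2 + (dx / cfg$cervix_axes[2])^2)
  rho_o <- sqrt((dy / cfg$os_axes[1])^2 + (dx / cfg$os_axes[2])^2)
  ew_c <- 1.5 / min(cfg$cervix_axes)
  ew_o <- 1.5 / min(cfg$os_axes)
  in_c <- smoothstep((1 - rho_c) / ew_c)
  in_o <- smoothstep((1 - rho_o) / ew_o)
  shade <- 1 - 0.25 * pmin(rho_c, 1)^2
  wt <- whitening_profile(t, cfg)
  H <- nrow(sy)
  W <- ncol(sy)
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    cerv <- pmin(.phantom_colors$cervix[ch] * wt, 1) * shade
    plane <- .phantom_colors$bg[ch] * (1 - in_c) + cerv * in_c
    plane <- plane * (1 - in_o) + .phantom_colors$os[ch] * in_o
    out[, , ch] <- plane
  }
  out
}

#' Generate a synthetic acetowhitening time sequence with ground truth
#'
#' Renders `n_frames` RGB frames in `[0, 1]`. Frame 1 is the reference scene;
#' every frame `t > 1` is the same scene transported by a rigid transform
#' (rotation about the image centre plus translation) drawn uniformly within
#' `(-max_rotation, max_rotation)` degrees and `(-max_translation,
#' max_translation)` pixels. The cervix brightens over time following
#' [whitening_profile()]; per-frame photometric gain jitter and Gaussian
#' noise are applied after the geometry, so the recorded transforms remain
#' exact. Frames are rendered analytically in transformed coordinates (no
#' resampling blur).
#'
#' Ground truth records, per frame, the rigid transform mapping frame-1
#' geometry to the frame, and a binary cervix mask. The frame-1 mask is the
#' rasterized cervix ellipse; each later mask is the frame-1 mask transported
#' by that frame's transform via nearest-neighbour resampling, so transported
#' re-rasterization reproduces the stored masks exactly.
#'
#' @param config a [phantom_config()].
#' @return a list with class `phantom_sequence`:
#'   \describe{
#'     \item{frames}{list of `H x W x 3` arrays in `[0, 1]` (class
#'       `time_sequence`).}
#'     \item{truth}{list with `transforms` (data frame: frame, rotation, dy,
#'       dx) and `masks` (list of binary matrices).}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
generate_sequence <- function(config) {
  validate_phantom_config(config)
  cfg <- config
  H <- cfg$height
  W <- cfg$width
  with_seed(cfg$seed, {
    rots <- c(0, runif(cfg$n_frames - 1, -cfg$max_rotation, cfg$max_rotation))
    dys <- c(0, runif(cfg$n_frames - 1, -cfg$max_translation, cfg$max_translation))
    dxs <- c(0, runif(cfg$n_frames - 1, -cfg$max_translation, cfg$max_translation))
    if (cfg$max_rotation == 0) rots[] <- 0
    if (cfg$max_translation == 0) {
      dys[] <- 0
      dxs[] <- 0
    }
    gains <- matrix(1, cfg$n_frames, 3)
    if (cfg$illumination_jitter > 0)
      gains[-1, ] <- 1 + runif((cfg$n_frames - 1) * 3,
                               -cfg$illumination_jitter, cfg$illumination_jitter)

    base_r <- matrix(rep(0:(H - 1), W), H, W)
    base_c <- matrix(rep(0:(W - 1), each = H), H, W)

    # frame-1 mask: analytic rasterization of the cervix ellipse
    dy0 <- base_r - cfg$cervix_center[1]
    dx0 <- base_c - cfg$cervix_center[2]
    mask1 <- (dy0 / cfg$cervix_axes[1])^2 + (dx0 / cfg$cervix_axes[2])^2
    mask1 <- (mask1 <= 1) + 0

    elastic <- NULL
    if (cfg$elastic_sigma > 0)
      elastic <- lapply(seq_len(cfg$n_frames), function(t)
        if (t == 1) zero_field(H, W) else smooth_random_field(H, W, cfg$elastic_sigma))

    frames <- vector("list", cfg$n_frames)
    masks <- vector("list", cfg$n_frames)
    for (t in seq_len(cfg$n_frames)) {
      # sample scene at T^{-1}(p): applies motion T to the rendered frame
      uin <- rigid_field(rots[t], dys[t], dxs[t], H, W, invert = TRUE)
      if (!is.null(elastic)) uin <- uin + elastic[[t]]
      img <- render_scene(base_r + uin[, , 1], base_c + uin[, , 2], cfg, t)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * gains[t, ch]
      if (cfg$noise_sigma > 0)
        img <- img + array(rnorm(length(img), 0, cfg$noise_sigma), dim(img))
      frames[[t]] <- clip01(img)
      masks[[t]] <- if (t == 1) mask1 else warp_mask(mask1, uin)
    }
    structure(list(
      frames = structure(frames, class = "time_sequence"),
      truth = list(
        transforms = data.frame(frame = seq_len(cfg$n_frames),
                                rotation = rots, dy = dys, dx = dxs),
        masks = masks
      ),
      config = cfg
    ), class = "phantom_sequence")
  })
}

# Smooth random displacement perturbation: coarse Gaussian grid upsampled
# bilinearly to full resolution, amplitude scaled to `sigma` pixels.
smooth_random_field <- function(height, width, sigma) {
  hc <- max(2L, height %/% 16L)
  wc <- max(2L, width %/% 16L)
  u <- array(rnorm(hc * wc * 2, 0, sigma), c(hc, wc, 2))
  up <- resize_bilinear_cpp(u, as.integer(height), as.integer(width))
  array(up, c(height, width, 2))
}

#' @export
print.phantom_sequence <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("phantom_sequence: %d frames of %dx%d, seed %d\n",
              cfg$n_frames, cfg$height, cfg$width, cfg$seed))
  cat(sprintf("  motion <= %.1f px / %.1f deg; whitening rate %.2f; noise sd %.3f\n",
              cfg$max_translation, cfg$max_rotation, cfg$whitening_rate,
              cfg$noise_sigma))
  invisible(x)
}
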