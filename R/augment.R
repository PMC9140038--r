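#' Photometric augmentation of a single RGB frame
#'
#' Applies one of four photometric augmentations: `color_shift` (additive
#' per-channel shift), `contrast` (scaling about mid-grey), `sharpen`
#' (unsharp masking) or `gaussian_noise`. Spatial augmentations are
#' deliberately unsupported: pixel coordinates never change, so any
#' ground-truth mask of the frame remains valid after augmentation.
#'
#' Magnitude semantics per kind (all identity at magnitude 0):
#' \describe{
#'   \item{color_shift}{scalar magnitude in `[0, 0.2]`: each channel is
#'     shifted by a seeded uniform draw in `[-magnitude, magnitude]`.
#'     Alternatively a length-3 numeric gives the exact per-channel shifts.}
#'   \item{contrast}{magnitude in `[0, 0.3]`: contrast factor drawn in
#'     `[1 - magnitude, 1 + magnitude]`, applied as
#'     `(x - 0.5) * factor + 0.5`.}
#'   \item{sharpen}{amount in `[0, 1]`: unsharp mask
#'     `x + amount * (x - blur(x))` with a Gaussian blur of sd 1 px.}
#'   \item{gaussian_noise}{noise sd in `[0, 0.1]` on the `[0, 1]` scale.}
#' }
#' Outputs are clipped to `[0, 1]` and deterministic given `seed`.
#'
#' @param frame `H x W x 3` array in `[0, 1]`.
#' @param kind one of `"color_shift"`, `"contrast"`, `"sharpen"`,
#'   `"gaussian_noise"`.
#' @param magnitude see details above.
#' @param seed integer seed for the stochastic kinds.
#' @return augmented `H x W x 3` array in `[0, 1]`.
#' @export
augment_frame <- function(frame, kind, magnitude, seed = 1L) {
  assert_image(frame)
  kinds <- c("color_shift", "contrast", "sharpen", "gaussian_noise")
  if (!kind %in% kinds)
    stop(sprintf("unknown augmentation kind '%s'", kind), call. = FALSE)
  max_mag <- c(color_shift = 0.2, contrast = 0.3, sharpen = 1, gaussian_noise = 0.1)
  if (any(magnitude < 0) || (length(magnitude) == 1L && magnitude > max_mag[[kind]]))
    stop(sprintf("magnitude out of range [0, %g] for '%s'", max_mag[[kind]], kind),
         call. = FALSE)
  with_seed(seed, {
    out <- switch(kind,
      color_shift = {
        shifts <- if (length(magnitude) == 3L) magnitude
                  else runif(3, -magnitude, magnitude)
        sweep(frame, 3, shifts, `+`)
      },
      contrast = {
        factor <- if (magnitude == 0) 1 else runif(1, 1 - magnitude, 1 + magnitude)
        (frame - 0.5) * factor + 0.5
      },
      sharpen = frame + magnitude * (frame - blur_rgb(frame, sigma = 1)),
      gaussian_noise = if (magnitude == 0) frame else
        frame + array(rnorm(length(frame), 0, magnitude), dim(frame))
    )
    clip01(out)
  })
}

# Gaussian blur per channel via a truncated 2-sd kernel (same padding, so
# borders are mildly attenuated; adequate for unsharp masking).
blur_rgb <- function(frame, sigma = 1) {
  k <- 2L * ceiling(2 * sigma) + 1L
  ax <- seq_len(k) - (k + 1) / 2
  g1 <- exp(-ax^2 / (2 * sigma^2))
  ker <- outer(g1, g1)
  ker <- ker / sum(ker)
  w <- array(ker, c(k, k, 1, 1))
  pad <- (k - 1L) %/% 2L
  out <- frame
  for (ch in seq_len(dim(frame)[3]))
    out[, , ch] <- conv2d_fw_cpp(array(frame[, , ch], c(dim(frame)[1:2], 1)),
                                 w, 0, 1L, pad)[, , 1]
  out
}

#' Expand a sequence into an augmented training pool
#'
#' Returns the originals plus `per_frame_copies` photometric variants of each
#' frame, with provenance. Augmentation kinds are drawn (seeded) from the
#' four allowed photometric kinds only; no spatial transform is ever applied.
#'
#' @param sequence a `time_sequence` (list of `H x W x 3` frames) or a
#'   `phantom_sequence`.
#' @param per_frame_copies number of augmented copies per frame (`>= 0`).
#' @param seed integer seed.
#' @param magnitudes named list of maximum magnitudes per kind; defaults to
#'   moderate values within each kind's documented range.
#' @return list with `frames` (the pool) and `provenance` (data frame:
#'   `source_frame`, `kind`, `magnitude`; originals have kind `"none"`).
#' @export
upsample_sequence <- function(sequence, per_frame_copies, seed = 1L,
                              magnitudes = list(color_shift = 0.1,
                                                contrast = 0.15,
                                                sharpen = 0.5,
                                                gaussian_noise = 0.02)) {
  frames <- as_frame_list(sequence)
  if (per_frame_copies < 0) stop("`per_frame_copies` must be >= 0", call. = FALSE)
  n <- length(frames)
  pool <- frames
  prov <- data.frame(source_frame = seq_len(n), kind = "none", magnitude = 0)
  if (per_frame_copies > 0) {
    kinds <- names(magnitudes)
    with_seed(seed, {
      draws_kind <- sample(kinds, n * per_frame_copies, replace = TRUE)
      draws_seed <- sample.int(.Machine$integer.max, n * per_frame_copies)
      k <- 0L
      for (copy in seq_len(per_frame_copies)) {
        for (t in seq_len(n)) {
          k <- k + 1L
          kind <- draws_kind[k]
          mag <- magnitudes[[kind]]
          pool[[length(pool) + 1L]] <- augment_frame(frames[[t]], kind, mag,
                                                     seed = draws_seed[k])
          prov <- rbind(prov, data.frame(source_frame = t, kind = kind,
                                         magnitude = mag))
        }
      }
    })
  }
  list(frames = pool, provenance = prov)
}

as_frame_list <- function(sequence) {
  if (inherits(sequence, "phantom_sequence")) return(sequence$frames)
  if (inherits(sequence, "time_sequence") || is.list(sequence)) return(sequence)
  stop("`sequence` must be a time_sequence or phantom_sequence", call. = FALSE)
}
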