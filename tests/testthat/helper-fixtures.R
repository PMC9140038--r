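# Small deterministic fixtures used across the suite.

random_mask <- function(h = 12, w = 12, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(h * w, 1, p), h, w) + 0
}

random_frame <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# A tiny rigid phantom at CPU-friendly scale for fast unit tests.
tiny_phantom <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(height = 48, width = 48, n_frames = 5,
         cervix_axes = c(16, 13), os_axes = c(4, 3),
         max_translation = 4, max_rotation = 3, seed = seed),
    list(...))
  generate_sequence(do.call(phantom_config, args))
}
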