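# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# (H, W) or (H, W, C) numeric array check
assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || !(length(dim(x)) %in% c(2L, 3L)))
    stop(sprintf("`%s` must be a 2-d or 3-d numeric array", name), call. = FALSE)
  invisible(x)
}

assert_same_hw <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("dimension mismatch: %s are %s vs %s", what,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")), call. = FALSE)
  invisible(NULL)
}

# Rec. 601 luma, used for the grayscale training/registration mode.
luminance <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

is_binary_mask <- function(m) {
  is.numeric(m) && length(dim(m)) == 2L && all(m %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
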