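#' Register every frame of a sequence to its first frame
#'
#' Inference: frame 1 is the untouched reference. For every later frame `t`,
#' each trained branch predicts a displacement field from the channel pair
#' (fixed = frame 1, moving = frame t) and the frame is backward-warped
#' channel-wise by those fields ([warp_rgb()]); intensities are clipped to
#' `[0, 1]`. In single-channel modes one branch predicts a single field that
#' is applied to all three colour planes, so the output remains an RGB frame.
#' An untrained model predicts near-zero fields and therefore returns the
#' input nearly unchanged (a warning is emitted when the mean field
#' magnitude is below 0.01 px).
#'
#' @param model an `rgb_registrar`, a single `branch_network`, or a
#'   `training_run` (its model and mode are used).
#' @param sequence `time_sequence`/`phantom_sequence`/list of frames at the
#'   model's build resolution.
#' @param mode `"rgb"` or one of the single-channel modes; inferred from a
#'   `training_run`, otherwise defaults to `"rgb"` for an `rgb_registrar`
#'   and `"grayscale"` for a bare branch.
#' @return an object of class `registered_sequence`: list with `frames`
#'   (frame 1 bit-identical to the input), `fields` (per frame, a list of
#'   per-channel `H x W x 2` fields; identically zero for frame 1) and
#'   `mode`.
#' @export
register_sequence <- function(model, sequence, mode = NULL) {
  if (inherits(model, "training_run")) {
    mode <- mode %||% model$mode
    model <- model$model
  }
  frames <- as_frame_list(sequence)
  if (length(frames) < 2L) stop("a sequence needs at least 2 frames", call. = FALSE)
  if (inherits(model, "rgb_registrar")) {
    mode <- mode %||% "rgb"
    branches <- unclass(model)[c("r", "g", "b")]
  } else if (inherits(model, "branch_network")) {
    mode <- mode %||% "grayscale"
    if (mode == "rgb")
      stop("rgb mode requires an rgb_registrar (three branches)", call. = FALSE)
    branches <- list(model)
  } else {
    stop("`model` must be an rgb_registrar, branch_network or training_run",
         call. = FALSE)
  }
  H <- dim(frames[[1]])[1]
  W <- dim(frames[[1]])[2]
  bh <- branches[[1]]
  if (H != bh$height || W != bh$width)
    stop(sprintf("sequence is %dx%d but model was trained at %dx%d",
                 H, W, bh$height, bh$width), call. = FALSE)

  n <- length(frames)
  out_frames <- frames
  n_fields <- if (mode == "rgb") 3L else 1L
  fields <- vector("list", n)
  fields[[1]] <- replicate(n_fields, zero_field(H, W), simplify = FALSE)
  ref_ch <- channels_for_mode(frames[[1]], mode)
  mag <- 0
  for (t in 2:n) {
    mov_ch <- channels_for_mode(frames[[t]], mode)
    ft <- lapply(seq_len(n_fields), function(b)
      predict_field(branches[[b]], ref_ch[[b]], mov_ch[[b]]))
    fields[[t]] <- ft
    if (mode == "rgb") {
      out_frames[[t]] <- clip01(warp_rgb(frames[[t]], ft))
    } else {
      wf <- frames[[t]]
      for (ch in 1:3) wf[, , ch] <- warp(frames[[t]][, , ch], ft[[1]])
      out_frames[[t]] <- clip01(wf)
    }
    mag <- mag + mean(abs(ft[[1]]))
  }
  if (mag / (n - 1) < 0.01)
    warning("predicted fields are near zero; is the model trained?", call. = FALSE)
  structure(list(frames = structure(out_frames, class = "time_sequence"),
                 fields = fields, mode = mode),
            class = "registered_sequence")
}

#' Transport a binary mask through predicted displacement fields
#'
#' Warps an evaluation mask with nearest-neighbour sampling by one designated
#' channel's field, keeping it strictly binary. Since the three colour
#' branches may disagree slightly, a channel policy selects which field
#' transports the mask; the default is the green channel (the plane with the
#' strongest epithelial contrast), and a single-field list is used as-is.
#'
#' @param mask binary `H x W` matrix.
#' @param fields list of per-channel `H x W x 2` fields (as stored per frame
#'   in a `registered_sequence`), or a single field.
#' @param channel_policy `"green"`, `"red"` or `"blue"`.
#' @return transported binary mask.
#' @export
transport_mask <- function(mask, fields, channel_policy = c("green", "red", "blue")) {
  channel_policy <- match.arg(channel_policy)
  if (is.list(fields)) {
    idx <- if (length(fields) == 1L) 1L
           else match(channel_policy, c("red", "green", "blue"))
    field <- fields[[idx]]
  } else {
    field <- fields
  }
  warp_mask(mask, field)
}

#' @export
print.registered_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("registered_sequence: %d frames of %dx%d (%s mode)\n",
              length(x$frames), d[1], d[2], x$mode))
  invisible(x)
}
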