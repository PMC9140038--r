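#' Load a time sequence from a directory of image frames
#'
#' Reads all PNG/TIFF frames in a directory, ordered by natural filename
#' sort, into a `time_sequence` of `H x W x 3` arrays on the `[0, 1]` scale
#' (grayscale images are replicated across channels; alpha channels are
#' dropped). Optionally resizes so the longer edge matches `long_edge`
#' (aspect ratio preserved, bilinear), then pads symmetrically by edge
#' replication to the nearest dimensions divisible by `pad_multiple` - the
#' network's total downsampling factor - recording the padding in the
#' manifest so it can be stripped from outputs.
#'
#' @param path directory containing >= 2 decodable frames of identical size.
#' @param long_edge optional target length in pixels for the longer edge.
#' @param pad_multiple pad dimensions up to a multiple of this (default 16);
#'   use 1 to disable.
#' @return list with `frames` (a `time_sequence`) and `manifest` (directory,
#'   ordered filenames, dimensions, padding, provenance).
#' @export
load_sequence <- function(path, long_edge = NULL, pad_multiple = 16L) {
  if (!dir.exists(path)) stop(sprintf("no such directory: %s", path), call. = FALSE)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  files <- natural_sort(files)
  if (length(files) < 2L)
    stop(sprintf("directory %s holds %d readable frames; need >= 2",
                 path, length(files)), call. = FALSE)
  frames <- lapply(file.path(path, files), read_frame)
  dims <- lapply(frames, function(f) dim(f)[1:2])
  if (length(unique(dims)) != 1L)
    stop(sprintf("mixed frame dimensions in %s: %s", path,
                 paste(unique(vapply(dims, paste, "", collapse = "x")),
                       collapse = " vs ")), call. = FALSE)
  oh <- dims[[1]][1]
  ow <- dims[[1]][2]
  if (!is.null(long_edge)) {
    scale <- long_edge / max(oh, ow)
    nh <- as.integer(round(oh * scale))
    nw <- as.integer(round(ow * scale))
    frames <- lapply(frames, function(f) {
      out <- resize_bilinear_cpp(f, nh, nw)
      array(out, c(nh, nw, 3))
    })
  } else {
    nh <- oh
    nw <- ow
  }
  pad <- pad_amounts(nh, nw, pad_multiple)
  if (any(unlist(pad) > 0))
    frames <- lapply(frames, pad_replicate, pad = pad)
  list(
    frames = structure(frames, class = "time_sequence"),
    manifest = list(directory = normalizePath(path), filenames = files,
                    height = dim(frames[[1]])[1], width = dim(frames[[1]])[2],
                    n_frames = length(frames),
                    original_height = oh, original_width = ow,
                    pad = pad, provenance = "external")
  )
}

natural_sort <- function(x) {
  key <- suppressWarnings(as.numeric(gsub("\\D", "", x)))
  key[is.na(key)] <- Inf
  x[order(key, x)]
}

read_frame <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png = png::readPNG(file),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF frames requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(file)
    },
    stop(sprintf("cannot decode '%s': unsupported format '%s'", file, ext),
         call. = FALSE)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  clip01(img)
}

pad_amounts <- function(h, w, m) {
  m <- as.integer(m)
  ph <- (m - h %% m) %% m
  pw <- (m - w %% m) %% m
  list(top = ph %/% 2L, bottom = ph - ph %/% 2L,
       left = pw %/% 2L, right = pw - pw %/% 2L)
}

pad_replicate <- function(frame, pad) {
  h <- dim(frame)[1]
  w <- dim(frame)[2]
  ri <- c(rep(1L, pad$top), seq_len(h), rep(h, pad$bottom))
  ci <- c(rep(1L, pad$left), seq_len(w), rep(w, pad$right))
  frame[ri, ci, , drop = FALSE]
}

#' Strip manifest-recorded padding from frames
#'
#' @param frames a `time_sequence` or single frame.
#' @param manifest the manifest returned by [load_sequence()].
#' @return frames cropped back to the pre-padding dimensions.
#' @export
strip_padding <- function(frames, manifest) {
  pad <- manifest$pad
  crop <- function(f) {
    h <- dim(f)[1]
    w <- dim(f)[2]
    f[(pad$top + 1L):(h - pad$bottom), (pad$left + 1L):(w - pad$right), ,
      drop = FALSE]
  }
  if (is.list(frames)) structure(lapply(frames, crop), class = "time_sequence")
  else crop(frames)
}

#' Write a time sequence (and optional masks / ground truth) to disk
#'
#' Frames are written as zero-padded numbered 8-bit PNGs
#' (`frame_01.png ...`); masks, if given, as 0/255 single-channel PNGs under
#' `masks/`; ground-truth rigid transforms, if given, as a
#' `ground_truth.json` sidecar. A `phantom_sequence` can be passed directly,
#' in which case its masks and transforms are written too.
#'
#' @param sequence a `time_sequence`, plain list of frames, or
#'   `phantom_sequence`.
#' @param path output directory (created if missing).
#' @param masks optional list of binary masks.
#' @param transforms optional data frame of per-frame rigid transforms.
#' @return the directory path, invisibly.
#' @export
write_sequence <- function(sequence, path, masks = NULL, transforms = NULL) {
  if (inherits(sequence, "phantom_sequence")) {
    masks <- masks %||% sequence$truth$masks
    transforms <- transforms %||% sequence$truth$transforms
    config <- sequence$config
    sequence <- sequence$frames
  } else {
    config <- NULL
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- length(sequence)
  wd <- max(2L, nchar(as.character(n)))
  for (t in seq_len(n)) {
    png::writePNG(sequence[[t]],
                  file.path(path, sprintf("frame_%0*d.png", wd, t)))
  }
  if (!is.null(masks)) {
    mdir <- file.path(path, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (t in seq_along(masks))
      png::writePNG(masks[[t]], file.path(mdir, sprintf("mask_%0*d.png", wd, t)))
  }
  if (!is.null(transforms)) {
    gt <- list(transforms = transforms)
    if (!is.null(config)) gt$config <- unclass(config)
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Load a directory of binary mask PNGs
#'
#' @param path directory of single-channel 0/255 PNGs (natural filename
#'   order).
#' @return list of binary `H x W` matrices.
#' @export
load_masks <- function(path) {
  files <- natural_sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE))
  if (length(files) == 0L) stop(sprintf("no mask PNGs in %s", path), call. = FALSE)
  lapply(file.path(path, files), function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    (m > 0.5) + 0
  })
}
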