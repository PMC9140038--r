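#' Backward-warp an image by a dense displacement field
#'
#' Resamples `image` at `p + u(p)` for every pixel `p` using bilinear
#' interpolation, i.e. `out(r, c) = image(r + u_y(r, c), c + u_x(r, c))`.
#' Sampling coordinates falling outside the image are clamped to the border
#' (clamp-to-edge), so a warp never introduces artificial black borders and
#' every output intensity stays within the input's intensity range. The
#' operation is differentiable with respect to both the image and the field;
#' the training loop uses the analytic gradients internally.
#'
#' @param image numeric `H x W` matrix (or `H x W x C` array) of intensities.
#' @param field displacement field: numeric `H x W x 2` array of per-pixel
#'   offsets in pixels; `field[, , 1]` is the row offset (dy), `field[, , 2]`
#'   the column offset (dx).
#' @return warped image with the same dimensions as `image`.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' u0 <- array(0, c(8, 8, 2))
#' identical(warp(img, u0), img)  # zero field is the exact identity
#' @export
warp <- function(image, field) {
  assert_image(image)
  check_field(field)
  assert_same_hw(image, field, "image and field")
  out <- warp_bilinear_fw_cpp(image, field)
  if (length(dim(image)) == 2L) dim(out) <- dim(image)
  out
}

#' Warp an RGB frame with one displacement field per channel
#'
#' Applies [warp()] independently to the red, green and blue planes, each with
#' its own field. The channels are deliberately not forced to share a field:
#' the per-channel registration branches may estimate (slightly) different
#' deformations for each chromatic component.
#'
#' @param frame numeric `H x W x 3` array.
#' @param fields list of exactly three `H x W x 2` displacement fields, in
#'   R, G, B order.
#' @return warped `H x W x 3` array.
#' @export
warp_rgb <- function(frame, fields) {
  assert_image(frame)
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("`frame` must be an H x W x 3 array", call. = FALSE)
  if (!is.list(fields) || length(fields) != 3L)
    stop("`fields` must be a list of three displacement fields", call. = FALSE)
  out <- frame
  for (ch in 1:3) out[, , ch] <- warp(frame[, , ch], fields[[ch]])
  out
}

#' Warp a binary mask with nearest-neighbour sampling
#'
#' Backward-warps a 0/1 mask by a displacement field using nearest-neighbour
#' lookup (clamp-to-edge), so the output remains strictly binary.
#'
#' @param mask numeric `H x W` matrix of 0/1 values.
#' @param field `H x W x 2` displacement field in pixels.
#' @return warped binary `H x W` matrix.
#' @export
warp_mask <- function(mask, field) {
  if (!is_binary_mask(mask)) stop("`mask` must be a binary H x W matrix", call. = FALSE)
  check_field(field)
  assert_same_hw(mask, field, "mask and field")
  warp_nearest_cpp(mask, field)
}

check_field <- function(field) {
  if (!is.numeric(field) || length(dim(field)) != 3L || dim(field)[3] != 2L)
    stop("displacement field must be an H x W x 2 numeric array", call. = FALSE)
  if (!all(is.finite(field)))
    stop("displacement field contains non-finite values", call. = FALSE)
  invisible(field)
}

zero_field <- function(height, width) array(0, c(height, width, 2))

#' Dense displacement field of a rigid transform
#'
#' Builds the `H x W x 2` backward-warp field of a rigid transform
#' `T(p) = R (p - center) + center + (dy, dx)` acting about the image centre
#' `((H-1)/2, (W-1)/2)` in 0-based row/column pixel coordinates. With
#' `invert = FALSE` the field samples at `T(p)`, so warping an image with it
#' *undoes* a scene motion by `T`; with `invert = TRUE` it samples at
#' `T^{-1}(p)`, which *applies* the motion to the image. Rotation is
#' counter-clockwise in (row, col) coordinates, in degrees.
#'
#' @param rotation rotation angle in degrees.
#' @param dy,dx translation in pixels (rows, columns).
#' @param height,width field dimensions.
#' @param invert if `TRUE`, build the field of the inverse transform.
#' @return `H x W x 2` displacement field in pixels.
#' @export
rigid_field <- function(rotation, dy, dx, height, width, invert = FALSE) {
  th <- rotation * pi / 180
  cy <- (height - 1) / 2
  cx <- (width - 1) / 2
  r <- matrix(rep(0:(height - 1), width), height, width) - cy
  c <- matrix(rep(0:(width - 1), each = height), height, width) - cx
  if (invert) {
    # T^{-1}(p) = R^T (p - center - t) + center
    r0 <- r - dy
    c0 <- c - dx
    sy <- cos(th) * r0 + sin(th) * c0
    sx <- -sin(th) * r0 + cos(th) * c0
  } else {
    sy <- cos(th) * r - sin(th) * c + dy
    sx <- sin(th) * r + cos(th) * c + dx
  }
  u <- array(0, c(height, width, 2))
  u[, , 1] <- sy - r
  u[, , 2] <- sx - c
  u
}

#' Save / load a displacement field as portable text
#'
#' Fields are stored as a plain-text container: a JSON header recording the
#' dimensions and the (dy, dx, backward-warp, pixel-units) convention,
#' followed by the values in a CSV table. Round-trips exactly at full double
#' precision.
#'
#' @param field `H x W x 2` displacement field.
#' @param path file path to write to / read from.
#' @return `read_field` returns the field; `write_field` its path, invisibly.
#' @export
write_field <- function(field, path) {
  check_field(field)
  d <- dim(field)
  header <- jsonlite::toJSON(list(
    height = d[1], width = d[2],
    components = c("dy", "dx"),
    convention = "backward-warp: out(p) = in(p + u(p)); units: pixels"
  ), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  utils::write.table(matrix(as.numeric(field), nrow = d[1] * d[2]),
                     con, row.names = FALSE, col.names = FALSE, sep = ",")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  vals <- utils::read.table(text = lines[-1], sep = ",")
  array(as.numeric(as.matrix(vals)), c(header$height, header$width, 2))
}
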