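# Image containers and plain-file IO.
#
# Images are plain numeric arrays of dimension L x L x 3 with intensities on
# the 0-255 scale, origin top-left, row-major (dim 1 = rows). Keeping the
# container a base array means every attack and metric composes with ordinary
# matrix algebra and the exact input gradients stay transparent.

#' Construct and validate an image tensor
#'
#' @param pixels numeric array of dimension `c(L, L, 3)` (or an `L x L`
#'   matrix, replicated across the three channels), values in `[0, 255]`.
#' @return a validated `L x L x 3` array of class `image_tensor`.
#' @export
image_tensor <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_advpercept("image must be an L x L x 3 array")
  d <- dim(pixels)
  if (d[1] != d[2]) stop_advpercept("images must be square (H = W = L)")
  if (d[1] < 16L) stop_advpercept("image side length must be at least 16 pixels")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop_advpercept("image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_advpercept("pixel intensities must lie in [0, 255]")
  structure(pixels, class = "image_tensor")
}

is_image_tensor <- function(x) inherits(x, "image_tensor") ||
  (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L)

image_side <- function(img) dim(img)[1]

#' Luminance channel of an RGB image
#'
#' Rec. 601 weights; used wherever a metric needs a single channel.
#' @param img `L x L x 3` array.
#' @return `L x L` matrix.
#' @export
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Write an image as a binary PPM (P6) file
#'
#' Stimuli are stored in the portable pixmap format: 8-bit, lossless for
#' rounded display images, readable everywhere without extra libraries.
#' Intensities are rounded to the nearest integer before writing.
#'
#' @param img image tensor.
#' @param path output file path (conventionally `.ppm`).
#' @export
write_ppm <- function(img, path) {
  L <- image_side(img)
  px <- round(clip(img, 0, 255))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", L, L), con, eos = NULL)
  # interleave RGB per pixel, row-major: channel fastest, then column, then row
  raw_vals <- as.raw(as.integer(aperm(px, c(3, 2, 1))))
  writeBin(raw_vals, con)
  invisible(path)
}

#' Read a binary PPM (P6) file written by [write_ppm()]
#' @param path file path.
#' @return an `image_tensor`.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "P6")) stop_advpercept("not a P6 PPM file: ", path)
  dims <- scan(con, what = integer(), n = 2, quiet = TRUE)
  maxv <- scan(con, what = integer(), n = 1, quiet = TRUE)
  if (maxv != 255L) stop_advpercept("only 8-bit PPM supported")
  raw_vals <- readBin(con, "raw", n = dims[1] * dims[2] * 3L)
  vals <- as.integer(raw_vals)
  arr <- aperm(array(vals, c(3L, dims[1], dims[2])), c(3, 2, 1))
  image_tensor(arr)
}

#' Write / read a perturbation losslessly as plain text
#'
#' Deltas may be fractional, so the 8-bit stimulus files cannot store them
#' exactly; these helpers keep full double precision in a plain-text grid.
#' @param delta `L x L x 3` array of per-pixel deltas.
#' @param path file path (conventionally `.delta.txt`).
#' @export
write_delta <- function(delta, path) {
  d <- dim(delta)
  header <- sprintf("advpercept-delta v1 %d %d %d", d[1], d[2], d[3])
  writeLines(c(header, format(as.vector(delta), digits = 17, scientific = TRUE)),
             path)
  invisible(path)
}

#' @rdname write_delta
#' @export
read_delta <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (!identical(hdr[1:2], c("advpercept-delta", "v1")))
    stop_advpercept("not an advpercept delta file: ", path)
  d <- as.integer(hdr[3:5])
  array(as.numeric(lines[-1]), d)
}
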