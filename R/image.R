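#' @keywords internal
abort_ic <- function(msg, class) {
  stop(structure(
    class = c(class, "inflocount_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Validate an RGB image array
#'
#' The package represents an RGB photograph as a numeric array of dimension
#' `H x W x 3` holding 8-bit channel values in `[0, 255]`, indexed
#' `[row, col, channel]` with 1-based pixel centres at integer coordinates.
#'
#' @param image object to validate.
#' @return the image, invisibly.
#' @export
validate_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    abort_ic("`image` must be an H x W x 3 array", "inflocount_error_invalid_input")
  d <- dim(image)
  if (d[1] < 1L || d[2] < 1L)
    abort_ic("`image` must have at least one row and one column",
             "inflocount_error_invalid_input")
  rng <- range(image)
  if (anyNA(image) || rng[1] < 0 || rng[2] > 255)
    abort_ic("`image` channel values must lie in [0, 255] with no NA",
             "inflocount_error_invalid_input")
  invisible(image)
}

#' Read an RGB image from PNG or JPEG
#'
#' 8-bit RGB is assumed; an alpha channel is dropped with a warning and
#' grayscale input is replicated across the three channels.
#'
#' @param path file path.
#' @return `H x W x 3` numeric array with values in `[0, 255]`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path))
    abort_ic(sprintf("image file not found: %s", path),
             "inflocount_error_invalid_input")
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) dat <- array(dat, dim = c(dim(dat), 1L))
  nc <- dim(dat)[3]
  if (nc == 4L || nc == 2L) {
    warning("alpha channel dropped from ", path)
    dat <- dat[, , seq_len(nc - 1L), drop = FALSE]
    nc <- dim(dat)[3]
  }
  if (nc == 1L) dat <- dat[, , c(1L, 1L, 1L), drop = FALSE]
  # EBImage stores (x = width, y = height, channel)
  out <- aperm(dat, c(2L, 1L, 3L)) * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  round(out)
}

#' Write an RGB image to PNG or JPEG (by file extension)
#'
#' @param image `H x W x 3` array, values in `[0, 255]`.
#' @param path destination; `.png` or `.jpg`/`.jpeg`.
#' @param quality JPEG quality (ignored for PNG).
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path, quality = 90L) {
  validate_rgb(image)
  dat <- aperm(image / 255, c(2L, 1L, 3L))
  img <- EBImage::Image(dat, colormode = "Color")
  EBImage::writeImage(img, path, quality = quality)
  invisible(path)
}

#' Convert an RGB image to CIE 1976 L*a*b*
#'
#' Channels are interpreted as sRGB under the D65 reference white (the default
#' tagging of phone JPEGs) and converted through XYZ.
#'
#' @param image `H x W x 3` array, values in `[0, 255]`.
#' @return list of three `H x W` matrices `L` (0-100), `a`, `b`.
#' @export
rgb_to_lab <- function(image) {
  validate_rgb(image)
  d <- dim(image)
  m <- matrix(as.numeric(image), ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(
    L = matrix(lab[, 1], d[1], d[2]),
    a = matrix(lab[, 2], d[1], d[2]),
    b = matrix(lab[, 3], d[1], d[2])
  )
}

#' Lightness channel of an RGB image
#'
#' Per-pixel CIE 1976 L* (0 = black, 100 = white) computed from sRGB/D65.
#' This is the channel in which flower highlights are detected: a
#' quasi-spherical flower reflects light towards the camera at one point,
#' which appears as a regional maximum of L*.
#'
#' @param image `H x W x 3` array, values in `[0, 255]`.
#' @return `H x W` numeric matrix with values in `[0, 100]`.
#' @export
to_lightness <- function(image) {
  rgb_to_lab(image)$L
}
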