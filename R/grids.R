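#' Single-channel intensity image with physical calibration
#'
#' The basic image container of the package: an unsigned-integer intensity
#' matrix together with its physical pixel pitch. All downstream geometry
#' (kernel sizes, search radii, area filters) is specified in micrometres and
#' converted to pixels through the pitch, so the same configuration applies
#' across magnifications.
#'
#' @param values Numeric matrix of non-negative intensities (rows = image
#'   rows). 12-bit data stored in 16-bit containers is accepted as-is; the
#'   thresholder is relative so absolute scale does not matter.
#' @param pixel_pitch_um Physical size of one (square) pixel in micrometres.
#'   Must be positive. Pitches of 2 um/pixel or more trigger a resolution
#'   warning: detection of nuclei and droplets degrades with the loss of
#'   resolution inherent in the local-mean convolution.
#' @param bit_depth 8 or 16. Defaults to 8 when all values fit, else 16.
#'
#' @return An object of class `pixel_grid`.
#' @export
pixel_grid <- function(values, pixel_pitch_um, bit_depth = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1 ||
      is.na(pixel_pitch_um) || pixel_pitch_um <= 0) {
    stop("`pixel_pitch_um` must be a single positive number", call. = FALSE)
  }
  if (is.null(bit_depth)) {
    bit_depth <- if (max(values, 0) <= 255) 8L else 16L
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  vmax <- 2^bit_depth - 1
  if (any(values < 0) || any(values > vmax)) {
    stop(sprintf("intensities outside the %d-bit range [0, %d]", bit_depth, vmax),
         call. = FALSE)
  }
  if (pixel_pitch_um >= 2) {
    warning(sprintf(
      "pixel pitch %.3g um/pixel is >= 2 um/pixel; detection is optimal below 2 um/pixel",
      pixel_pitch_um), call. = FALSE)
  }
  structure(
    list(values = values, pixel_pitch_um = pixel_pitch_um, bit_depth = bit_depth),
    class = "pixel_grid"
  )
}

#' @export
dim.pixel_grid <- function(x) dim(x$values)

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d, %d-bit, %.4g um/pixel, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$bit_depth, x$pixel_pitch_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Thresholded foreground mask
#'
#' A binary image over the alphabet \{0, 255\}: the output of [binarize()].
#' Keeping the 255 convention (rather than 0/1) preserves the thresholder's
#' published output contract and makes masks directly viewable as images.
#'
#' @param values Numeric matrix containing only 0 and 255.
#' @param pixel_pitch_um Physical pixel pitch in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, pixel_pitch_um) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!all(values %in% c(0, 255))) {
    stop("a binary mask may only contain 0 and 255", call. = FALSE)
  }
  if (pixel_pitch_um <= 0) stop("`pixel_pitch_um` must be positive", call. = FALSE)
  structure(
    list(values = values, pixel_pitch_um = pixel_pitch_um),
    class = "binary_mask"
  )
}

#' @export
dim.binary_mask <- function(x) dim(x$values)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %.4g um/pixel, %d foreground px (%.1f%%)\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch_um,
              sum(x$values > 0), 100 * mean(x$values > 0)))
  invisible(x)
}

#' Paired nuclei + lipid channels of one imaging field
#'
#' @param nuclei,lipid [pixel_grid] objects of identical dimensions and pitch.
#' @return An object of class `two_channel_image`.
#' @export
two_channel_image <- function(nuclei, lipid) {
  stopifnot(inherits(nuclei, "pixel_grid"), inherits(lipid, "pixel_grid"))
  if (!identical(dim(nuclei$values), dim(lipid$values))) {
    stop("calibration error: nuclei and lipid channels differ in shape (",
         paste(dim(nuclei$values), collapse = "x"), " vs ",
         paste(dim(lipid$values), collapse = "x"), ")", call. = FALSE)
  }
  if (!isTRUE(all.equal(nuclei$pixel_pitch_um, lipid$pixel_pitch_um))) {
    stop("calibration error: nuclei and lipid channels differ in pixel pitch",
         call. = FALSE)
  }
  structure(list(nuclei = nuclei, lipid = lipid), class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d, %.4g um/pixel\n",
              nrow(x$nuclei$values), ncol(x$nuclei$values),
              x$nuclei$pixel_pitch_um))
  invisible(x)
}

#' RGB brightfield image (Oil Red O + haematoxylin)
#'
#' @param red,green,blue Numeric matrices of identical shape.
#' @param pixel_pitch_um Physical pixel pitch in micrometres.
#' @param bit_depth Bit depth shared by all three channels (default 8).
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(red, green, blue, pixel_pitch_um, bit_depth = 8L) {
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue))) {
    stop("input error: RGB channels differ in shape", call. = FALSE)
  }
  vmax <- 2^bit_depth - 1
  for (ch in list(red, green, blue)) {
    if (any(ch < 0) || any(ch > vmax)) {
      stop(sprintf("RGB values outside the %d-bit range", bit_depth), call. = FALSE)
    }
  }
  if (pixel_pitch_um <= 0) stop("`pixel_pitch_um` must be positive", call. = FALSE)
  structure(
    list(red = red, green = green, blue = blue,
         pixel_pitch_um = pixel_pitch_um, bit_depth = as.integer(bit_depth)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d, %d-bit, %.4g um/pixel\n",
              nrow(x$red), ncol(x$red), x$bit_depth, x$pixel_pitch_um))
  invisible(x)
}
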