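#' Build the normalised 2D Gaussian kernel used by the local thresholder
#'
#' Constructs a z-by-z Gaussian weight matrix on the centred integer lattice,
#' with the bandwidth tied to the kernel size by
#' \deqn{\sigma = 0.3\,((z-1)/2 - 1) + 0.8,}
#' and normalised so the weights sum to one. Tying sigma to z means a single
#' physical kernel size fully determines the filter; the scaling is the
#' OpenCV `getGaussianKernel` convention and keeps the effective support of
#' the Gaussian proportional to the window.
#'
#' @param size_px Odd positive integer kernel edge length z, in pixels.
#' @return A list of class `gaussian_kernel` with elements `size_px`, `sigma`
#'   and `weights` (a `size_px` x `size_px` matrix summing to 1).
#' @export
#' @examples
#' k <- make_gaussian_kernel(3)
#' k$sigma          # 0.8
#' sum(k$weights)   # 1
make_gaussian_kernel <- function(size_px) {
  if (!is.numeric(size_px) || length(size_px) != 1 || is.na(size_px) ||
      size_px < 1 || size_px != as.integer(size_px) || size_px %% 2 == 0) {
    stop("`size_px` must be an odd positive integer", call. = FALSE)
  }
  size_px <- as.integer(size_px)
  sigma <- 0.3 * ((size_px - 1) / 2 - 1) + 0.8
  half <- (size_px - 1L) / 2L
  ax <- seq(-half, half)
  g1 <- exp(-ax^2 / (2 * sigma^2))
  w <- outer(g1, g1)
  w <- w / sum(w)
  structure(list(size_px = size_px, sigma = sigma, weights = w),
            class = "gaussian_kernel")
}

#' Convert a physical kernel size to an odd pixel count
#'
#' Rounds `kernel_size_um / pixel_pitch_um` to the nearest integer, then bumps
#' even results up by one and enforces a floor of 3 px so the window always
#' has a centre pixel and a neighbourhood.
#'
#' @param kernel_size_um Physical kernel extent in micrometres.
#' @param pixel_pitch_um Pixel pitch in micrometres per pixel.
#' @return An odd integer >= 3.
#' @export
#' @examples
#' kernel_size_px(33, 1)     # 33
#' kernel_size_px(33, 0.65)  # 51
kernel_size_px <- function(kernel_size_um, pixel_pitch_um) {
  if (kernel_size_um <= 0 || pixel_pitch_um <= 0) {
    stop("kernel size and pixel pitch must be positive", call. = FALSE)
  }
  n <- round(kernel_size_um / pixel_pitch_um)
  if (n %% 2 == 0) n <- n + 1
  as.integer(max(n, 3))
}

# Separable Gaussian-weighted local mean with replicate-edge padding.
# The 2D kernel is an outer product of its 1D profile, so the convolution is
# done as two passes of shift-and-add over the padded matrix: exact
# arithmetic (no FFT), O(z) matrix additions per axis.
gaussian_local_mean <- function(values, kernel) {
  z <- kernel$size_px
  half <- (z - 1L) / 2L
  nr <- nrow(values); nc <- ncol(values)
  if (z > nr || z > nc) {
    stop(sprintf("kernel (%d px) larger than image (%d x %d)", z, nr, nc),
         call. = FALSE)
  }
  g1 <- kernel$weights[half + 1L, ]
  g1 <- g1 / sum(g1)  # unit-sum 1D profile; outer(g1, g1) reproduces weights
  if (half == 0L) return(values)

  # replicate-pad rows, convolve down columns
  pad_r <- rbind(
    values[rep(1L, half), , drop = FALSE],
    values,
    values[rep(nr, half), , drop = FALSE]
  )
  acc <- matrix(0, nr, nc)
  for (k in seq_len(z)) {
    acc <- acc + g1[k] * pad_r[(k - 1L) + seq_len(nr), , drop = FALSE]
  }
  # replicate-pad cols, convolve across rows
  pad_c <- cbind(
    acc[, rep(1L, half), drop = FALSE],
    acc,
    acc[, rep(nc, half), drop = FALSE]
  )
  out <- matrix(0, nr, nc)
  for (k in seq_len(z)) {
    out <- out + g1[k] * pad_c[, (k - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

#' Local Gaussian-mean threshold field
#'
#' For every pixel, the threshold is the Gaussian-weighted mean of its
#' z-by-z neighbourhood (the convolution of the unit-sum kernel of
#' [make_gaussian_kernel()] with the image), minus an optional constant
#' offset. Borders are handled by replicate-edge padding, which avoids the
#' spurious dark rims that zero padding would create.
#'
#' @param image A [pixel_grid()].
#' @param kernel A `gaussian_kernel` from [make_gaussian_kernel()].
#' @param offset Constant subtracted from the local mean (default 0).
#' @return A list of class `threshold_field` with a `values` matrix the same
#'   shape as the input.
#' @export
local_threshold_field <- function(image, kernel, offset = 0) {
  stopifnot(inherits(image, "pixel_grid"), inherits(kernel, "gaussian_kernel"))
  t_field <- gaussian_local_mean(image$values, kernel) - offset
  structure(list(values = t_field, offset = offset), class = "threshold_field")
}

#' Adaptive local binarisation of a channel
#'
#' The thresholding step at the heart of the pipeline: a pixel is foreground
#' (255) if and only if its intensity strictly exceeds the Gaussian-weighted
#' mean of its neighbourhood. Because the comparison is against a local
#' mean, stains are detected by their prominence over their surroundings,
#' which is what makes the method robust to heavy, spatially varying
#' background in overconfluent cultures. The strict inequality means a
#' perfectly flat image yields an empty mask.
#'
#' @param image A [pixel_grid()].
#' @param kernel_size_um Physical kernel size in micrometres. Defaults of
#'   33 (nuclei) and 66 (lipid droplets) work well when kernels are two to
#'   three times the typical object group size.
#' @param offset Constant subtracted from the local mean before the
#'   comparison (default 0, the strict local-mean contract). Because the
#'   comparison is `In > mean - offset`, a strict mean comparison flecks
#'   roughly half of any near-flat noisy region into foreground; a negative
#'   offset of about twice the camera-noise SD raises the effective
#'   threshold and suppresses those flecks.
#' @return A [binary_mask()] the same shape as the input.
#' @export
#' @examples
#' img <- pixel_grid(matrix(0, 16, 16), pixel_pitch_um = 1)
#' img$values[8, 8] <- 200
#' mask <- binarize(img, kernel_size_um = 5)
#' sum(mask$values == 255)  # 1: only the bright pixel exceeds its local mean
binarize <- function(image, kernel_size_um, offset = 0) {
  stopifnot(inherits(image, "pixel_grid"))
  z <- kernel_size_px(kernel_size_um, image$pixel_pitch_um)
  kernel <- make_gaussian_kernel(z)
  t_field <- local_threshold_field(image, kernel, offset = offset)
  out <- matrix(0, nrow(image$values), ncol(image$values))
  out[image$values > t_field$values] <- 255
  binary_mask(out, image$pixel_pitch_um)
}
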