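#' Unmix an Oil Red O / haematoxylin RGB image into lipid + nuclei channels
#'
#' Converts a colour brightfield image into the two-channel form consumed by
#' the rest of the pipeline, by computing per-pixel colour biases:
#' the lipid channel is the red bias `max(0, R - max(G, B))` and the nuclei
#' channel the blue bias `max(0, B - max(R, G))`. Subtracting the maximum of
#' the other two channels makes white/grey background cancel exactly and
#' attenuates pixels where the red and blue stains overlap (purple), which is
#' why colour imaging reads lower than fluorescence on dense cultures. No
#' optical-density stain deconvolution is attempted; the method is an
#' RGB-space difference by design (see the methods vignette for the
#' alternative).
#'
#' @param rgb An [rgb_image()].
#' @return A [two_channel_image()] whose `lipid` channel carries the red bias
#'   and whose `nuclei` channel carries the blue bias.
#' @export
#' @examples
#' r <- matrix(c(255, 128), 1, 2); g <- matrix(c(0, 128), 1, 2)
#' b <- matrix(c(0, 128), 1, 2)
#' tc <- unmix_oro_haematoxylin(rgb_image(r, g, b, pixel_pitch_um = 1))
#' tc$lipid$values   # 255 for the pure-red pixel, 0 for the grey pixel
unmix_oro_haematoxylin <- function(rgb) {
  stopifnot(inherits(rgb, "rgb_image"))
  lipid <- pmax(rgb$red - pmax(rgb$green, rgb$blue), 0)
  nuclei <- pmax(rgb$blue - pmax(rgb$red, rgb$green), 0)
  two_channel_image(
    nuclei = pixel_grid(nuclei, rgb$pixel_pitch_um, bit_depth = rgb$bit_depth),
    lipid = pixel_grid(lipid, rgb$pixel_pitch_um, bit_depth = rgb$bit_depth)
  )
}
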