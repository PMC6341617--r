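#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Lipid-score histogram of a well
#'
#' The standard per-well view: nucleus counts over lipid score, a vertical
#' line at the mean lipid score, and the adipogenic score annotated in the
#' corner.
#'
#' @param object A `well_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot well_result
#' @export
autoplot.well_result <- function(object, ...) {
  if (!object$valid) stop("cannot plot an empty well", call. = FALSE)
  df <- tibble::tibble(s = object$scores$s)
  label <- sprintf("adipogenic score: %.1f%%", object$adipogenic_score)
  ggplot2::ggplot(df, ggplot2::aes(x = s)) +
    ggplot2::geom_histogram(bins = length(object$histogram$counts),
                            fill = "seagreen", colour = "grey30",
                            linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$mean_lipid_score,
                        colour = "grey50", linewidth = 0.8) +
    ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.05, vjust = 1.5,
                      label = label) +
    ggplot2::labs(
      title = sprintf("Well %s (%d nuclei)", object$well_id, object$n_nuclei),
      x = "lipid score", y = "nuclei"
    ) +
    ggplot2::theme_minimal()
}

#' Droplet radius distribution
#'
#' @param object A `droplet_summary` from [summarize_radii()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot droplet_summary
#' @export
autoplot.droplet_summary <- function(object, ...) {
  if (object$n_droplets == 0) stop("no droplets to plot", call. = FALSE)
  h <- object$radius_histogram
  mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
  df <- tibble::tibble(radius_um = mids, count = h$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = radius_um, y = count)) +
    ggplot2::geom_col(fill = "goldenrod", colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$mean_radius_um,
                        colour = "grey50", linewidth = 0.8) +
    ggplot2::labs(x = "droplet radius (um)", y = "droplets",
                  title = sprintf("%d droplets, mean radius %.2f um",
                                  object$n_droplets, object$mean_radius_um)) +
    ggplot2::theme_minimal()
}

#' Adipogenic scores across wells
#'
#' @param results List of `well_result` objects or a [well_summary()] tibble.
#' @return A ggplot bar chart of adipogenic score per well.
#' @export
plot_adipogenic_scores <- function(results) {
  tbl <- if (inherits(results, "data.frame")) results else well_summary(results)
  ggplot2::ggplot(dplyr::filter(tbl, valid),
                  ggplot2::aes(x = well_id, y = adipogenic_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "well", y = "adipogenic score (%)") +
    ggplot2::theme_minimal()
}
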