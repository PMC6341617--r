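#' Score one nucleus for nearby lipid droplets
#'
#' The per-nucleus lipid score is \eqn{S = P_T \times I_s}: the fraction of
#' the searched area that is above the lipid threshold (\eqn{P_T}) times the
#' mean lipid intensity over those foreground pixels (\eqn{I_s}). The search
#' region is the nucleus bounding box dilated by `search_radius_um` on every
#' side (3 um by default, a good balance of false positives and negatives at
#' high cell density) and clipped to the image. Defining \eqn{I_s} as a mean
#' rather than a sum keeps S bounded by the bit-depth maximum and
#' independent of nucleus size, so one gate value applies across the
#' population; `intensity_mode = "sum"` restores the summed alternative.
#'
#' @param nucleus One row of a region tibble (see [label_components()]),
#'   with status `"kept"`.
#' @param lipid A [pixel_grid()] of the lipid channel.
#' @param lipid_mask The [binary_mask()] of the lipid channel.
#' @param search_radius_um Dilation of the bounding box, in micrometres.
#' @param intensity_mode `"mean"` (default) or `"sum"`.
#' @return A one-row tibble with `nucleus_label`, `centroid_row`,
#'   `centroid_col`, `p_t`, `i_s`, `s`, `differentiated` (NA until gated).
#' @export
score_nucleus <- function(nucleus, lipid, lipid_mask, search_radius_um = 3,
                          intensity_mode = c("mean", "sum")) {
  intensity_mode <- match.arg(intensity_mode)
  stopifnot(inherits(lipid, "pixel_grid"), inherits(lipid_mask, "binary_mask"))
  if (!identical(dim(lipid$values), dim(lipid_mask$values))) {
    stop("lipid image and mask differ in shape", call. = FALSE)
  }
  nr <- nrow(lipid$values); nc <- ncol(lipid$values)
  r_px <- as.integer(round(search_radius_um / lipid$pixel_pitch_um))
  r0 <- max(nucleus$min_row - r_px, 1L)
  r1 <- min(nucleus$max_row - 1L + r_px, nr)
  c0 <- max(nucleus$min_col - r_px, 1L)
  c1 <- min(nucleus$max_col - 1L + r_px, nc)
  if (r1 < r0 || c1 < c0) stop("internal error: empty search region", call. = FALSE)
  sub_i <- lipid$values[r0:r1, c0:c1, drop = FALSE]
  sub_m <- lipid_mask$values[r0:r1, c0:c1, drop = FALSE] > 0
  n_total <- length(sub_m)
  n_fg <- sum(sub_m)
  p_t <- n_fg / n_total
  i_s <- if (n_fg == 0) 0 else {
    if (intensity_mode == "mean") mean(sub_i[sub_m]) else sum(sub_i[sub_m])
  }
  tibble::tibble(
    nucleus_label = nucleus$label,
    centroid_row = nucleus$centroid_row,
    centroid_col = nucleus$centroid_col,
    p_t = p_t, i_s = i_s, s = p_t * i_s,
    differentiated = NA
  )
}

#' Score every kept nucleus in a field
#'
#' Applies [score_nucleus()] to all regions with status `"kept"`.
#' Overlapping search regions of neighbouring nuclei may both count the same
#' droplet pixels; droplets are tied to nuclei by proximity only, with no
#' exclusive assignment.
#'
#' @param regions Region tibble after [filter_regions()].
#' @inheritParams score_nucleus
#' @return A tibble with one row per kept nucleus.
#' @export
score_nuclei <- function(regions, lipid, lipid_mask, search_radius_um = 3,
                         intensity_mode = c("mean", "sum")) {
  intensity_mode <- match.arg(intensity_mode)
  kept <- dplyr::filter(regions, status == "kept")
  if (nrow(kept) == 0) {
    return(tibble::tibble(
      nucleus_label = integer(), centroid_row = double(),
      centroid_col = double(), p_t = double(), i_s = double(), s = double(),
      differentiated = logical()
    ))
  }
  purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    score_nucleus(kept[i, ], lipid, lipid_mask,
                  search_radius_um = search_radius_um,
                  intensity_mode = intensity_mode)
  })
}

#' Gate lipid scores into differentiated / non-differentiated
#'
#' A nucleus is marked differentiated when its lipid score strictly exceeds
#' the gate threshold. The comparison is strict, so a score exactly at the
#' gate is non-differentiated.
#'
#' @param scores Score tibble from [score_nuclei()].
#' @param gate_threshold Non-negative cutoff on the lipid-score scale.
#' @return The score tibble with `differentiated` set.
#' @export
gate_scores <- function(scores, gate_threshold) {
  if (!is.numeric(gate_threshold) || length(gate_threshold) != 1 ||
      is.na(gate_threshold) || gate_threshold < 0) {
    stop("`gate_threshold` must be a single non-negative number", call. = FALSE)
  }
  dplyr::mutate(scores, differentiated = s > gate_threshold)
}

#' Derive a gate threshold from undifferentiated control scores
#'
#' No universal gate value exists — lipid scores are in arbitrary
#' fluorescence units that depend on staining and exposure — so when control
#' wells are available the default gate is `mean(s) + k * sd(s)` over the
#' pooled control nuclei.
#'
#' @param control_scores Score tibble(s) of undifferentiated control nuclei.
#' @param k Number of standard deviations above the control mean (default 2).
#' @return A single gate threshold value.
#' @export
derive_gate_threshold <- function(control_scores, k = 2) {
  s <- control_scores$s
  if (length(s) == 0) stop("analysis error: no control nuclei to derive a gate from",
                           call. = FALSE)
  mean(s) + k * stats::sd(s)
}

#' Pool gated scores of a well into its summary
#'
#' Concatenates the per-field score tables of one well (fields carry no
#' weight: the pooled result is identical to scoring the concatenated
#' nucleus list), then computes the adipogenic score — the percentage of
#' nuclei whose lipid score exceeded the gate — the mean lipid score, and a
#' histogram of scores over `[0, max(s)]`.
#'
#' @param well_id Well label, e.g. `"B07"`.
#' @param per_field_scores A list of gated score tibbles, one per field (a
#'   single tibble is accepted).
#' @param histogram_bins Number of uniform histogram bins (default 50;
#'   presentation only, never used in any computation).
#' @param gate_threshold The gate that was applied, recorded for reporting.
#' @return An object of class `well_result`: a list with `well_id`,
#'   `scores`, `n_nuclei`, `adipogenic_score` (percent, `NA` for an empty
#'   well, which is flagged `valid = FALSE`), `mean_lipid_score`,
#'   `histogram` (list of `breaks` and `counts`), `gate_threshold`.
#' @export
aggregate_well <- function(well_id, per_field_scores, histogram_bins = 50,
                           gate_threshold = NA_real_) {
  if (inherits(per_field_scores, "data.frame")) {
    per_field_scores <- list(per_field_scores)
  }
  if (length(per_field_scores) == 0) {
    stop("analysis error: a well needs at least one field", call. = FALSE)
  }
  scores <- dplyr::bind_rows(per_field_scores)
  n <- nrow(scores)
  if (n == 0) {
    res <- list(
      well_id = well_id, scores = scores, n_nuclei = 0L,
      adipogenic_score = NA_real_, mean_lipid_score = NA_real_,
      histogram = list(breaks = numeric(), counts = integer()),
      gate_threshold = gate_threshold, valid = FALSE
    )
    return(structure(res, class = "well_result"))
  }
  if (any(is.na(scores$differentiated))) {
    stop("scores must be gated (gate_scores) before aggregation", call. = FALSE)
  }
  smax <- max(scores$s)
  breaks <- seq(0, max(smax, .Machine$double.eps), length.out = histogram_bins + 1)
  counts <- as.integer(graphics::hist(scores$s, breaks = breaks, plot = FALSE,
                                      include.lowest = TRUE, right = TRUE)$counts)
  res <- list(
    well_id = well_id,
    scores = scores,
    n_nuclei = n,
    adipogenic_score = 100 * sum(scores$differentiated) / n,
    mean_lipid_score = mean(scores$s),
    histogram = list(breaks = breaks, counts = counts),
    gate_threshold = gate_threshold,
    valid = TRUE
  )
  structure(res, class = "well_result")
}

#' @export
print.well_result <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<well_result> %s: no nuclei (invalid)\n", x$well_id))
  } else {
    cat(sprintf(
      "<well_result> %s: %d nuclei, adipogenic score %.2f%%, mean lipid score %.3g (gate %.3g)\n",
      x$well_id, x$n_nuclei, x$adipogenic_score, x$mean_lipid_score,
      x$gate_threshold))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-nucleus scores of a well as a tibble
#'
#' @param x A `well_result`.
#' @param ... Unused.
#' @return The per-nucleus score tibble with a `well_id` column prepended.
#' @method tidy well_result
#' @export
tidy.well_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(well_id = rep(x$well_id, nrow(x$scores))),
                   x$scores)
}

#' One-row summary of a well
#'
#' @param x A `well_result`.
#' @param ... Unused.
#' @return A one-row tibble: `well_id`, `n_nuclei`, `adipogenic_score`,
#'   `mean_lipid_score`, `gate_threshold`, `valid`.
#' @method glance well_result
#' @export
glance.well_result <- function(x, ...) {
  tibble::tibble(
    well_id = x$well_id, n_nuclei = x$n_nuclei,
    adipogenic_score = x$adipogenic_score,
    mean_lipid_score = x$mean_lipid_score,
    gate_threshold = x$gate_threshold, valid = x$valid
  )
}

#' Summarise a list of wells as one tibble
#'
#' @param results List of `well_result` objects.
#' @return A tibble with one row per well (see [glance.well_result()]).
#' @export
well_summary <- function(results) {
  purrr::map_dfr(results, glance)
}

#' Rank wells against control wells
#'
#' Computes, for every non-control well, the difference between its
#' adipogenic score and the mean adipogenic score of the control wells
#' (e.g. DMSO vehicle), in percentage points, sorted descending — the usual
#' hit-ranking view of an image-based screen.
#'
#' @param wells A list of `well_result` objects or a summary tibble from
#'   [well_summary()].
#' @param control_ids Character vector of control well ids.
#' @return A tibble `well_id`, `adipogenic_score`, `control_mean`, `delta`,
#'   sorted by `delta` descending.
#' @export
compare_to_control <- function(wells, control_ids) {
  tbl <- if (inherits(wells, "data.frame")) wells else well_summary(wells)
  ctrl <- dplyr::filter(tbl, well_id %in% control_ids, valid)
  if (nrow(ctrl) == 0) {
    stop("analysis error: no valid control wells among ",
         paste(control_ids, collapse = ", "), call. = FALSE)
  }
  ctrl_mean <- mean(ctrl$adipogenic_score)
  tbl |>
    dplyr::filter(!well_id %in% control_ids, valid) |>
    dplyr::transmute(
      well_id,
      adipogenic_score,
      control_mean = ctrl_mean,
      delta = adipogenic_score - ctrl_mean
    ) |>
    dplyr::arrange(dplyr::desc(delta))
}

#' Whole-image intensity baseline (plate-reader surrogate)
#'
#' The naive readout a fluorescence plate reader would give: the mean
#' lipid-channel intensity over the whole field, with no segmentation
#' (`mode = "lipid_mean"`, the default), or the ratio of total lipid to
#' total nuclear signal (`mode = "lipid_over_nuclei"`). Provided as a
#' comparison baseline — these are the quantities that saturated clumps and
#' non-specific staining corrupt, which per-nucleus scoring is designed to
#' resist.
#'
#' @param field A [two_channel_image()].
#' @param mode `"lipid_mean"` or `"lipid_over_nuclei"`.
#' @return A single number (intensity units, or unitless for the ratio).
#' @export
naive_intensity_ratio <- function(field, mode = c("lipid_mean", "lipid_over_nuclei")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "two_channel_image"))
  if (mode == "lipid_mean") {
    mean(field$lipid$values)
  } else {
    sum(field$lipid$values) / max(sum(field$nuclei$values), 1)
  }
}
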