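#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. All physical
#' parameters are in micrometres and converted per-image through the pixel
#' pitch.
#'
#' @param manifest Path to the plate manifest CSV ([read_manifest()]).
#' @param out_dir Optional output directory; when given, per-well CSV,
#'   per-nucleus CSV, a JSON summary and (optionally) histogram figures are
#'   written there.
#' @param nuclei_kernel_um,lipid_kernel_um Adaptive-threshold kernel sizes
#'   (defaults 33 and 66: two to three times the typical object group size).
#' @param offset Additive offset of the local threshold (default 0, the
#'   published strict local-mean comparison).
#' @param min_area_um2,max_area_um2,max_aspect_ratio Region filter bounds
#'   ([filter_regions()]).
#' @param min_seed_distance_um Watershed seed separation ([split_touching()]).
#' @param search_radius_um Lipid search radius beyond the nucleus bounding
#'   box (default 3).
#' @param gate_threshold Explicit lipid-score gate. When `NULL`, the gate is
#'   derived as mean + `gate_k` x SD of the pooled scores of the control
#'   wells (`control_ids` must then be non-empty).
#' @param gate_k Multiplier for the control-derived gate (default 2).
#' @param intensity_mode `"mean"` or `"sum"` (see [score_nucleus()]).
#' @param histogram_bins Histogram bins per well (default 50).
#' @param control_ids Character vector of control well ids.
#' @param write_figures Write a per-well histogram PNG (default `FALSE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, out_dir = NULL,
                            nuclei_kernel_um = 33, lipid_kernel_um = 66,
                            offset = 0,
                            min_area_um2 = 20, max_area_um2 = 500,
                            max_aspect_ratio = 3, min_seed_distance_um = 6,
                            search_radius_um = 3,
                            gate_threshold = NULL, gate_k = 2,
                            intensity_mode = c("mean", "sum"),
                            histogram_bins = 50,
                            control_ids = character(),
                            write_figures = FALSE) {
  intensity_mode <- match.arg(intensity_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Analyse one two-channel field
#'
#' The per-field core of the pipeline: binarise both channels with the
#' local Gaussian-mean thresholder, watershed-split and label the nuclei
#' mask, annotate regions with size/shape exclusion statuses, and score
#' every kept nucleus for nearby lipid signal. Gating is left to the
#' caller so that a control-derived gate can be applied plate-wide.
#'
#' @param field A [two_channel_image()].
#' @param config A [pipeline_config()].
#' @return A list: `scores` (ungated tibble from [score_nuclei()]),
#'   `regions` (annotated region tibble), `exclusions` (named counts per
#'   status).
#' @export
analyze_field <- function(field, config = pipeline_config()) {
  stopifnot(inherits(field, "two_channel_image"))
  nuc_mask <- binarize(field$nuclei, config$nuclei_kernel_um, config$offset)
  nuc_mask <- split_touching(nuc_mask, config$min_seed_distance_um)
  regions <- label_components(nuc_mask) |>
    filter_regions(config$min_area_um2, config$max_area_um2,
                   config$max_aspect_ratio)
  lip_mask <- binarize(field$lipid, config$lipid_kernel_um, config$offset)
  scores <- score_nuclei(regions, field$lipid, lip_mask,
                         search_radius_um = config$search_radius_um,
                         intensity_mode = config$intensity_mode)
  list(
    scores = scores,
    regions = regions,
    exclusions = c(
      kept = sum(regions$status == "kept"),
      too_small = sum(regions$status == "too_small"),
      too_large = sum(regions$status == "too_large"),
      misshapen = sum(regions$status == "misshapen")
    )
  )
}

#' Run the full plate pipeline
#'
#' Reads the manifest, processes every field (unmixing colour fields,
#' binarising, splitting, filtering, scoring), derives or applies the gate,
#' pools fields into wells, and (when `out_dir` is set) writes the per-well
#' CSV, per-nucleus CSV, JSON summary, an exclusion log, and optional
#' histogram figures. A failing field does not abort the plate: its well is
#' flagged partial in the exclusion log and processing continues.
#'
#' @param config A [pipeline_config()] with `manifest` set.
#' @return A named list of `well_result` objects (one per well), with the
#'   per-field exclusion log attached as attribute `"exclusions"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$manifest)) {
    stop("usage error: `manifest` must be set in the pipeline config", call. = FALSE)
  }
  records <- read_manifest(config$manifest)
  if (nrow(records) == 0) {
    stop("usage error: the manifest contains no fields", call. = FALSE)
  }

  field_scores <- vector("list", nrow(records))
  logs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    res <- tryCatch({
      field <- read_field(rec)
      analyze_field(field, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("well %s field %d failed: %s (well flagged partial)",
                      rec$well_id, rec$field_index, conditionMessage(res)),
              call. = FALSE)
      logs[[i]] <- tibble::tibble(
        well_id = rec$well_id, field_index = rec$field_index,
        kept = NA_integer_, too_small = NA_integer_, too_large = NA_integer_,
        misshapen = NA_integer_, failed = TRUE)
      next
    }
    field_scores[[i]] <- res$scores
    ex <- res$exclusions
    logs[[i]] <- tibble::tibble(
      well_id = rec$well_id, field_index = rec$field_index,
      kept = ex[["kept"]], too_small = ex[["too_small"]],
      too_large = ex[["too_large"]], misshapen = ex[["misshapen"]],
      failed = FALSE)
  }
  exclusion_log <- dplyr::bind_rows(logs)

  gate <- config$gate_threshold
  if (is.null(gate)) {
    if (length(config$control_ids) == 0) {
      stop("usage error: set `gate_threshold` or provide `control_ids` ",
           "to derive the gate from control wells", call. = FALSE)
    }
    ctrl_idx <- which(records$well_id %in% config$control_ids)
    ctrl_scores <- dplyr::bind_rows(field_scores[ctrl_idx])
    gate <- derive_gate_threshold(ctrl_scores, k = config$gate_k)
  }

  wells <- unique(records$well_id)
  results <- lapply(wells, function(w) {
    idx <- which(records$well_id == w)
    gated <- lapply(field_scores[idx], function(sc) {
      if (is.null(sc)) return(NULL)
      gate_scores(sc, gate)
    })
    gated <- gated[!vapply(gated, is.null, logical(1))]
    if (length(gated) == 0) gated <- list(score_nuclei(empty_regions(),
      pixel_grid(matrix(0, 3, 3), records$pixel_pitch_um[idx[1]]),
      binary_mask(matrix(0, 3, 3), records$pixel_pitch_um[idx[1]])))
    aggregate_well(w, gated, histogram_bins = config$histogram_bins,
                   gate_threshold = gate)
  })
  names(results) <- wells
  attr(results, "exclusions") <- exclusion_log

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_well_csv(
      results,
      file.path(config$out_dir, "wells.csv"),
      per_nucleus_path = file.path(config$out_dir, "nuclei.csv"),
      json_path = file.path(config$out_dir, "summary.json")
    )
    readr::write_csv(exclusion_log, file.path(config$out_dir, "exclusions.csv"))
    if (isTRUE(config$write_figures)) {
      for (res in results) {
        if (!res$valid) next
        fig <- file.path(config$out_dir, sprintf("well_%s_hist.png", res$well_id))
        try({
          p <- ggplot2::autoplot(res)
          ggplot2::ggsave(fig, p, width = 6, height = 4, dpi = 120)
        }, silent = TRUE)
      }
    }
  }
  results
}

#' Run a screening comparison against control wells
#'
#' Runs the plate pipeline, then ranks every treated well by the difference
#' of its adipogenic score from the control mean ([compare_to_control()]).
#'
#' @param config A [pipeline_config()] with `control_ids` set.
#' @param control_ids Optional override of `config$control_ids`.
#' @return The hit tibble (also written to `hits.csv` when `out_dir` is
#'   set), with the well results attached as attribute `"wells"`.
#' @export
run_screen <- function(config, control_ids = NULL) {
  if (!is.null(control_ids)) config$control_ids <- control_ids
  if (length(config$control_ids) == 0) {
    stop("usage error: `control_ids` required for screening", call. = FALSE)
  }
  results <- run_pipeline(config)
  hits <- compare_to_control(results, config$control_ids)
  if (!is.null(config$out_dir)) {
    readr::write_csv(hits, file.path(config$out_dir, "hits.csv"))
  }
  attr(hits, "wells") <- results
  hits
}
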