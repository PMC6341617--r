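#' Read a single-channel image file into a pixel grid
#'
#' Reads baseline TIFF (8/16-bit) or PNG. Integer values are preserved
#' exactly; 16-bit data is never rescaled. The physical pitch always comes
#' from the caller (normally the plate manifest): resolution tags embedded
#' in exported TIFFs are ignored as unreliable across export paths.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_pitch_um Pixel pitch in micrometres per pixel.
#' @return A [pixel_grid()].
#' @export
read_image_grid <- function(path, pixel_pitch_um) {
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- attr(x, "bits.per.sample")
    if (is.null(depth)) depth <- if (max(x) > 255) 16L else 8L
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    x <- round(x * (2^depth - 1))
  } else {
    stop("input error: unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) x <- x[, , 1] else
      stop("input error: expected a single-channel image: ", path, call. = FALSE)
  }
  pixel_grid(matrix(as.numeric(x), nrow(x), ncol(x)), pixel_pitch_um,
             bit_depth = as.integer(depth))
}

#' Write a pixel grid to a TIFF or PNG file
#'
#' The written file round-trips losslessly through [read_image_grid()].
#'
#' @param grid A [pixel_grid()].
#' @param path Destination path; format chosen by extension.
#' @export
write_image_grid <- function(grid, path) {
  stopifnot(inherits(grid, "pixel_grid"))
  vmax <- 2^grid$bit_depth - 1
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    ok <- tiff::writeTIFF(grid$values / vmax, path,
                          bits.per.sample = grid$bit_depth)
  } else if (ext == "png") {
    ok <- png::writePNG(grid$values / vmax, path)
  } else {
    stop("I/O error: unsupported image format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read an RGB image file
#'
#' @param path Path to a 3-channel TIFF or PNG.
#' @param pixel_pitch_um Pixel pitch in micrometres per pixel.
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path, pixel_pitch_um) {
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # multi-channel TIFFs always come back scaled to [0, 1]
    x <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(x, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
    x <- round(x * (2^depth - 1))
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    x <- round(x * (2^depth - 1))
  } else {
    stop("input error: unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(x)) != 3L || dim(x)[3] < 3L) {
    stop("input error: expected a 3-channel RGB image: ", path, call. = FALSE)
  }
  rgb_image(x[, , 1], x[, , 2], x[, , 3], pixel_pitch_um,
            bit_depth = as.integer(depth))
}

#' Write an RGB image
#'
#' @param rgb An [rgb_image()].
#' @param path Destination `.tif`/`.png` path.
#' @export
write_rgb_image <- function(rgb, path) {
  stopifnot(inherits(rgb, "rgb_image"))
  vmax <- 2^rgb$bit_depth - 1
  arr <- array(c(rgb$red, rgb$green, rgb$blue) / vmax,
               dim = c(nrow(rgb$red), ncol(rgb$red), 3))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = rgb$bit_depth)
  } else if (ext == "png") {
    png::writePNG(arr, path)
  } else {
    stop("I/O error: unsupported image format: ", path, call. = FALSE)
  }
  invisible(path)
}

manifest_columns <- c("well_id", "field_index", "nuclei_path", "lipid_path",
                      "rgb_path", "pixel_pitch_um")

# render doubles as shortest-17-significant-digit decimal text so written
# values re-read bit-exactly
format_doubles <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))
  ))
}

#' Read a plate manifest
#'
#' The manifest is a CSV with header
#' `well_id,field_index,nuclei_path,lipid_path,rgb_path,pixel_pitch_um`.
#' Each row describes one imaging field in either fluorescence mode
#' (`nuclei_path` + `lipid_path` populated) or colour mode (`rgb_path`
#' populated); the two modes may be mixed within one manifest. Relative
#' paths are resolved against the manifest's directory. Records are
#' returned sorted by `(well_id, field_index)` regardless of input order.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble of validated field records with an added `mode` column
#'   (`"fluorescence"` or `"oro"`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("input error: manifest not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          well_id = readr::col_character(),
                          field_index = readr::col_integer(),
                          nuclei_path = readr::col_character(),
                          lipid_path = readr::col_character(),
                          rgb_path = readr::col_character(),
                          pixel_pitch_um = readr::col_double(),
                          .default = readr::col_character()
                        ))
  extra <- setdiff(names(df), manifest_columns)
  if (length(extra) > 0) {
    stop("manifest error: unknown column(s) ", paste(extra, collapse = ", "),
         "; accepted columns are ", paste(manifest_columns, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing) > 0) {
    stop("manifest error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  blank <- function(x) is.na(x) | x == ""
  fluo <- !blank(df$nuclei_path) & !blank(df$lipid_path) & blank(df$rgb_path)
  oro <- blank(df$nuclei_path) & blank(df$lipid_path) & !blank(df$rgb_path)
  bad <- which(!(fluo | oro))
  if (length(bad) > 0) {
    stop("manifest error: row(s) ", paste(bad, collapse = ", "),
         " must populate either nuclei_path+lipid_path or rgb_path (not both)",
         call. = FALSE)
  }
  key <- paste(df$well_id, df$field_index)
  if (anyDuplicated(key)) {
    stop("manifest error: duplicate (well_id, field_index): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (any(is.na(df$pixel_pitch_um) | df$pixel_pitch_um <= 0)) {
    stop("manifest error: pixel_pitch_um must be a positive number in every row",
         call. = FALSE)
  }
  base <- dirname(path)
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  df |>
    dplyr::mutate(
      nuclei_path = resolve(nuclei_path),
      lipid_path = resolve(lipid_path),
      rgb_path = resolve(rgb_path),
      mode = ifelse(fluo, "fluorescence", "oro")
    ) |>
    dplyr::arrange(well_id, field_index)
}

#' Read the image(s) of one field record
#'
#' In fluorescence mode, reads the two channel files and pairs them; in
#' colour mode, reads the RGB file and unmixes it through
#' [unmix_oro_haematoxylin()], so either mode yields the same two-channel
#' form. Channel shape mismatches are calibration errors; a pitch of
#' 2 um/pixel or more warns (resolution is sub-optimal) but proceeds.
#'
#' @param record One row of the manifest tibble from [read_manifest()].
#' @return A [two_channel_image()].
#' @export
read_field <- function(record) {
  if (record$mode == "oro") {
    rgb <- read_rgb_image(record$rgb_path, record$pixel_pitch_um)
    return(unmix_oro_haematoxylin(rgb))
  }
  nuc <- read_image_grid(record$nuclei_path, record$pixel_pitch_um)
  lip <- read_image_grid(record$lipid_path, record$pixel_pitch_um)
  two_channel_image(nuclei = nuc, lipid = lip)
}

#' Write per-well (and optionally per-nucleus) results to CSV
#'
#' One row per well: nucleus count, mean lipid score, adipogenic score and
#' the gate threshold used. Numbers are written as full-precision decimal
#' text, so a written file re-read reproduces the scores exactly.
#'
#' @param results Non-empty list of `well_result` objects.
#' @param path Destination CSV path for the per-well table.
#' @param per_nucleus_path Optional path for the long-format per-nucleus
#'   table (one row per scored nucleus across all wells).
#' @param json_path Optional path for a JSON summary mirroring the CSV.
#' @return Invisibly, the per-well tibble.
#' @export
write_well_csv <- function(results, path, per_nucleus_path = NULL,
                           json_path = NULL) {
  if (length(results) == 0) {
    stop("I/O error: no well results to write", call. = FALSE)
  }
  tbl <- well_summary(results)
  readr::write_csv(format_doubles(tbl), path, na = "")
  if (!is.null(per_nucleus_path)) {
    per_nuc <- purrr::map_dfr(results, tidy)
    readr::write_csv(format_doubles(per_nuc), per_nucleus_path, na = "")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(tbl, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(tbl)
}
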