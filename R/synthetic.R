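#' Specify a synthetic two-channel adipogenesis scene
#'
#' The generator's defaults describe a realistic differentiating culture at
#' the densities where per-nucleus scoring earns its keep: 200 nuclei in a
#' 640x640 um field (~490 cells/mm^2), nuclei ~10 um across, and — for each
#' differentiated cell — a cluster of bright lipid droplets (radius ~1.5 um)
#' placed inside the 3 um neighbourhood of its nucleus. Background has a
#' constant level, a smooth linear gradient and soft blotches, emulating the
#' heavy non-uniform background staining of overconfluent monolayers. Dead
#' cells are rendered as thin sub-minimum-area slivers of high aspect ratio;
#' an optional clump region saturates both channels, as multilayer
#' aggregates that adsorb both dyes do.
#'
#' Every differentiated cell receives `8 + Poisson(droplets_per_cell - 8)`
#' droplets, so no differentiated cell is dropletless; this keeps the two
#' score modes fully separated, which is what a well-stained culture with a
#' bright neutral-lipid dye looks like.
#'
#' @param width_px,height_px Field size in pixels.
#' @param pixel_pitch_um Pixel pitch (default 1 um/pixel).
#' @param n_nuclei Number of live nuclei.
#' @param differentiated_fraction Fraction of nuclei carrying droplets;
#'   exactly `round(differentiated_fraction * n_nuclei)` are flagged.
#' @param nucleus_radius_um,nucleus_intensity Mean and SD (length-2 vectors)
#'   of nucleus equivalent radius (um) and peak intensity.
#' @param droplets_per_cell Mean droplet count per differentiated cell
#'   (must be >= 8; see above).
#' @param droplet_radius_um,droplet_intensity Mean and SD of droplet radius
#'   (um) and intensity.
#' @param background Length-3 vector: base level, linear-gradient amplitude,
#'   blotch amplitude (intensity units).
#' @param n_dead_cells Number of misshapen sub-minimum nuclei to plant.
#' @param clump Optional list `(row, col, radius_um)`: a disc saturated in
#'   both channels.
#' @param noise_sd Additive Gaussian noise SD.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; the scene is a pure function of the spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 640, height_px = 640, pixel_pitch_um = 1,
                       n_nuclei = 200, differentiated_fraction = 0.5,
                       nucleus_radius_um = c(5, 0.8),
                       nucleus_intensity = c(150, 20),
                       droplets_per_cell = 12,
                       droplet_radius_um = c(1.5, 0.4),
                       droplet_intensity = c(180, 20),
                       background = c(20, 15, 10),
                       n_dead_cells = 0,
                       clump = NULL,
                       noise_sd = 3,
                       bit_depth = 8,
                       seed = 1) {
  if (differentiated_fraction < 0 || differentiated_fraction > 1) {
    stop("`differentiated_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (droplets_per_cell < 8) stop("`droplets_per_cell` must be >= 8", call. = FALSE)
  stopifnot(nucleus_radius_um[1] > 0, droplet_radius_um[1] > 0,
            pixel_pitch_um > 0, n_nuclei >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

# anti-aliased ellipse rendering: coverage from the signed pixel distance to
# the ellipse boundary, soft over ~1 px. Returns the local patch and its
# bounds; the caller subassigns in place to avoid whole-canvas copies.
ellipse_patch <- function(nr, nc, cr, cc, a_px, b_px, theta, intensity) {
  ext <- ceiling(max(a_px, b_px)) + 2L
  r0 <- max(1L, floor(cr - ext)); r1 <- min(nr, ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(nc, ceiling(cc + ext))
  if (r1 < r0 || c1 < c0) return(NULL)
  rs <- r0:r1; cs <- c0:c1
  dy <- matrix(rs - cr, length(rs), length(cs))
  dx <- matrix(cs - cc, length(rs), length(cs), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a_px
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_px
  d <- sqrt(u^2 + v^2)
  cover <- pmin(pmax((1 - d) * min(a_px, b_px) + 0.5, 0), 1)
  list(rs = rs, cs = cs, values = intensity * cover)
}

smooth_background <- function(nr, nc, base, grad_amp, blotch_amp) {
  gr <- stats::runif(1, 0, 2 * pi)
  rows <- matrix(seq_len(nr) / nr, nr, nc)
  cols <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
  bg <- base + grad_amp * (cos(gr) * rows + sin(gr) * cols - 0.5 * (cos(gr) + sin(gr)) + 0.5)
  for (i in 1:4) {
    br <- stats::runif(1, 1, nr); bc <- stats::runif(1, 1, nc)
    sd_b <- stats::runif(1, 0.1, 0.25) * min(nr, nc)
    amp <- stats::runif(1, 0.3, 1) * blotch_amp
    rows_d <- matrix(seq_len(nr) - br, nr, nc)
    cols_d <- matrix(seq_len(nc) - bc, nr, nc, byrow = TRUE)
    bg <- bg + amp * exp(-(rows_d^2 + cols_d^2) / (2 * sd_b^2))
  }
  bg
}

#' Generate a synthetic scene with full ground truth
#'
#' Renders the two fluorescence channels described by a [scene_spec()] and
#' returns them with the planted ground truth: nucleus positions, radii,
#' differentiated flags, droplet geometry, dead-cell labels and the clump
#' disc. The output is bit-identical for identical specs (seed included).
#' Nuclei are placed without overlap by rejection sampling; impossibly dense
#' specs raise an error advising a lower density. Every planted droplet
#' centre lies within the 3 um dilation of its parent nucleus's bounding
#' box, checked at generation time, so the default search radius can see it.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (a [two_channel_image()]) and
#'   `truth` (list: `nuclei` tibble, `droplets` tibble, `clump`,
#'   `differentiated_fraction`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  nr <- spec$height_px; nc <- spec$width_px
  pitch <- spec$pixel_pitch_um
  vmax <- 2^spec$bit_depth - 1
  nuclei_ch <- matrix(0, nr, nc)
  lipid_ch <- matrix(0, nr, nc)

  # --- place live nuclei without overlap ---
  n <- spec$n_nuclei
  radii_um <- pmax(stats::rnorm(n, spec$nucleus_radius_um[1], spec$nucleus_radius_um[2]), 2)
  radii_px <- radii_um / pitch
  centers <- matrix(NA_real_, n, 2)
  if (n > 0) {
    batch <- 50L
    for (i in seq_len(n)) {
      placed <- FALSE
      m <- radii_px[i] + 2
      for (round in seq_len(ceiling(10000 / batch))) {
        cr <- stats::runif(batch, m, nr - m)
        cc <- stats::runif(batch, m, nc - m)
        if (i == 1) {
          hit <- 1L
        } else {
          prev <- seq_len(i - 1)
          d2 <- outer(centers[prev, 1], cr, "-")^2 +
            outer(centers[prev, 2], cc, "-")^2
          min_d <- radii_px[prev] + radii_px[i] + 2
          ok <- colSums(d2 < min_d^2) == 0
          hit <- which(ok)[1]
        }
        if (!is.na(hit)) {
          centers[i, ] <- c(cr[hit], cc[hit]); placed <- TRUE; break
        }
      }
      if (!placed) {
        stop("density error: could not place all nuclei without overlap; ",
             "reduce n_nuclei or enlarge the field", call. = FALSE)
      }
    }
  }
  thetas <- stats::runif(n, 0, pi)
  ecc <- stats::runif(n, 1, 1.4)   # major/minor axis ratio at constant area
  a_px <- radii_px * sqrt(ecc)
  b_px <- radii_px / sqrt(ecc)
  nuc_int <- pmin(pmax(stats::rnorm(n, spec$nucleus_intensity[1],
                                    spec$nucleus_intensity[2]), 30), vmax)
  n_diff <- round(spec$differentiated_fraction * n)
  diff_flag <- rep(FALSE, n)
  if (n_diff > 0) diff_flag[sample.int(n, n_diff)] <- TRUE

  for (i in seq_len(n)) {
    p <- ellipse_patch(nr, nc, centers[i, 1], centers[i, 2],
                       a_px[i], b_px[i], thetas[i], nuc_int[i])
    if (!is.null(p)) nuclei_ch[p$rs, p$cs] <- pmax(nuclei_ch[p$rs, p$cs], p$values)
  }

  # --- droplets near differentiated nuclei ---
  search_px <- 3 / pitch
  droplets <- list()
  for (i in which(diff_flag)) {
    k <- 8L + stats::rpois(1, spec$droplets_per_cell - 8)
    # half-extents of the rotated ellipse bounding box
    ex <- sqrt(a_px[i]^2 * sin(thetas[i])^2 + b_px[i]^2 * cos(thetas[i])^2)
    ey <- sqrt(a_px[i]^2 * cos(thetas[i])^2 + b_px[i]^2 * sin(thetas[i])^2)
    rd_um <- pmax(stats::rnorm(k, spec$droplet_radius_um[1], spec$droplet_radius_um[2]), 0.5)
    rd_px <- rd_um / pitch
    span_r <- pmax(ey + search_px - rd_px, 0.5)
    span_c <- pmax(ex + search_px - rd_px, 0.5)
    drow <- centers[i, 1] + stats::runif(k, -span_r, span_r)
    dcol <- centers[i, 2] + stats::runif(k, -span_c, span_c)
    di <- pmin(pmax(stats::rnorm(k, spec$droplet_intensity[1],
                                 spec$droplet_intensity[2]), 40), vmax)
    stopifnot(all(abs(drow - centers[i, 1]) <= ey + search_px + 1e-9),
              all(abs(dcol - centers[i, 2]) <= ex + search_px + 1e-9))
    for (j in seq_len(k)) {
      p <- ellipse_patch(nr, nc, drow[j], dcol[j], rd_px[j], rd_px[j], 0, di[j])
      if (!is.null(p)) lipid_ch[p$rs, p$cs] <- pmax(lipid_ch[p$rs, p$cs], p$values)
    }
    droplets[[length(droplets) + 1]] <- tibble::tibble(
      nucleus_label = i, row = drow, col = dcol, radius_um = rd_um
    )
  }
  droplets <- if (length(droplets)) dplyr::bind_rows(droplets) else
    tibble::tibble(nucleus_label = integer(), row = double(),
                   col = double(), radius_um = double())

  # --- dead cells: thin high-aspect slivers below the minimum area ---
  nd <- spec$n_dead_cells
  dead <- NULL
  if (nd > 0) {
    # placed clear of live nuclei so a sliver never fuses with a kept region
    dr <- numeric(nd); dc <- numeric(nd)
    sliver_px <- 4 / pitch
    for (i in seq_len(nd)) {
      placed <- FALSE
      for (attempt in seq_len(10000)) {
        rr <- stats::runif(1, sliver_px + 2, nr - sliver_px - 2)
        cc2 <- stats::runif(1, sliver_px + 2, nc - sliver_px - 2)
        clear <- (n == 0 || all(
          sqrt((centers[, 1] - rr)^2 + (centers[, 2] - cc2)^2) >=
            radii_px + sliver_px + 3)) &&
          (i == 1 || all(
            sqrt((dr[seq_len(i - 1)] - rr)^2 +
                 (dc[seq_len(i - 1)] - cc2)^2) >= 2 * sliver_px + 2))
        if (clear) { dr[i] <- rr; dc[i] <- cc2; placed <- TRUE; break }
      }
      if (!placed) {
        stop("density error: could not place dead cells clear of nuclei",
             call. = FALSE)
      }
    }
    dth <- stats::runif(nd, 0, pi)
    for (i in seq_len(nd)) {
      # a = 4 um, b = 0.6 um: area ~7.5 um^2 (< 20), aspect ~6.7 (> 3)
      p <- ellipse_patch(nr, nc, dr[i], dc[i], 4 / pitch, 0.6 / pitch,
                         dth[i], spec$nucleus_intensity[1])
      if (!is.null(p)) nuclei_ch[p$rs, p$cs] <- pmax(nuclei_ch[p$rs, p$cs], p$values)
    }
    dead <- tibble::tibble(row = dr, col = dc)
  }

  # --- background, clump, noise ---
  bg <- spec$background
  nuclei_ch <- nuclei_ch + smooth_background(nr, nc, bg[1], bg[2], bg[3])
  lipid_ch <- lipid_ch + smooth_background(nr, nc, bg[1], bg[2], bg[3])

  if (spec$noise_sd > 0) {
    nuclei_ch <- nuclei_ch + stats::rnorm(nr * nc, 0, spec$noise_sd)
    lipid_ch <- lipid_ch + stats::rnorm(nr * nc, 0, spec$noise_sd)
  }

  # the clump is applied after noise: a saturated detector reads full scale
  clump_mask <- NULL
  if (!is.null(spec$clump)) {
    cl <- spec$clump
    rr <- matrix(seq_len(nr) - cl$row, nr, nc)
    cc2 <- matrix(seq_len(nc) - cl$col, nr, nc, byrow = TRUE)
    clump_mask <- (rr^2 + cc2^2) <= (cl$radius_um / pitch)^2
    nuclei_ch[clump_mask] <- vmax
    lipid_ch[clump_mask] <- vmax
  }

  nuclei_ch <- matrix(pmin(pmax(round(nuclei_ch), 0), vmax), nr, nc)
  lipid_ch <- matrix(pmin(pmax(round(lipid_ch), 0), vmax), nr, nc)

  truth <- list(
    nuclei = tibble::tibble(
      label = seq_len(n),
      row = centers[, 1], col = centers[, 2],
      radius_um = radii_um, differentiated = diff_flag
    ),
    droplets = droplets,
    dead_cells = dead,
    clump = spec$clump,
    clump_mask = clump_mask,
    differentiated_fraction = spec$differentiated_fraction
  )
  list(
    image = two_channel_image(
      nuclei = pixel_grid(nuclei_ch, pitch, bit_depth = spec$bit_depth),
      lipid = pixel_grid(lipid_ch, pitch, bit_depth = spec$bit_depth)
    ),
    truth = truth
  )
}

#' Render a fluorescence scene as an Oil Red O / haematoxylin RGB image
#'
#' Re-renders a two-channel scene as a colour brightfield image on a white
#' background: lipid signal appears red (absorbing green and blue), nuclear
#' signal blue-purple (absorbing green and red). The `overlap` coefficient
#' models how much each stain's colour bleeds towards the other — at 0 the
#' stains are pure red and pure blue and the bias-difference unmixing
#' recovers the channels exactly (up to clamping); as overlap grows the
#' recovered biases shrink by `(1 - overlap)`, and at full overlap they
#' vanish, the degenerate case in which colour imaging cannot separate the
#' stains.
#'
#' @param scene Output of [generate_scene()] (or any [two_channel_image()]).
#' @param overlap Bleed coefficient in \[0, 1\].
#' @return An 8-bit [rgb_image()].
#' @export
render_oro <- function(scene, overlap = 0.2) {
  img <- if (inherits(scene, "two_channel_image")) scene else scene$image
  stopifnot(overlap >= 0, overlap <= 1)
  vmax <- 2^img$lipid$bit_depth - 1
  L <- img$lipid$values / vmax * 255
  N <- img$nuclei$values / vmax * 255
  clamp <- function(x) pmin(pmax(round(x), 0), 255)
  red <- clamp(255 - (1 - overlap) * N)
  green <- clamp(255 - L - N)
  blue <- clamp(255 - (1 - overlap) * L)
  rgb_image(red, green, blue, img$lipid$pixel_pitch_um, bit_depth = 8L)
}

#' Simulate a plate of wells and write it to disk
#'
#' Generates one scene per (well, field), writes the channel images as TIFF
#' files (or a single RGB TIFF in `"oro"` mode), a `manifest.csv` in the
#' format [read_manifest()] consumes, and a `truth.json` with the planted
#' differentiated fraction per well.
#'
#' @param wells A tibble/data.frame with columns `well_id` and
#'   `differentiated_fraction`, optionally `n_fields` (default 1).
#' @param dir Output directory (created if needed).
#' @param base_spec A [scene_spec()] providing everything except fraction
#'   and seed.
#' @param mode `"fluorescence"` or `"oro"`.
#' @param overlap Stain overlap for `"oro"` mode.
#' @param seed Base seed; field seeds are derived deterministically.
#' @return The manifest tibble (invisibly the path is `dir/manifest.csv`).
#' @export
simulate_plate <- function(wells, dir, base_spec = scene_spec(),
                           mode = c("fluorescence", "oro"), overlap = 0.2,
                           seed = 1) {
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!"n_fields" %in% names(wells)) wells$n_fields <- 1L
  rows <- list()
  for (w in seq_len(nrow(wells))) {
    for (f in seq_len(wells$n_fields[w])) {
      fseed <- (seed * 1000L + w * 29L + f * 7L) %% .Machine$integer.max
      sp <- base_spec
      sp$differentiated_fraction <- wells$differentiated_fraction[w]
      sp$seed <- fseed
      scene <- generate_scene(sp)
      wid <- wells$well_id[w]
      if (mode == "fluorescence") {
        np <- sprintf("%s_f%02d_nuclei.tif", wid, f)
        lp <- sprintf("%s_f%02d_lipid.tif", wid, f)
        write_image_grid(scene$image$nuclei, file.path(dir, np))
        write_image_grid(scene$image$lipid, file.path(dir, lp))
        rows[[length(rows) + 1]] <- tibble::tibble(
          well_id = wid, field_index = f - 1L, nuclei_path = np,
          lipid_path = lp, rgb_path = NA_character_,
          pixel_pitch_um = sp$pixel_pitch_um)
      } else {
        rgb <- render_oro(scene, overlap = overlap)
        rp <- sprintf("%s_f%02d_rgb.tif", wid, f)
        write_rgb_image(rgb, file.path(dir, rp))
        rows[[length(rows) + 1]] <- tibble::tibble(
          well_id = wid, field_index = f - 1L, nuclei_path = NA_character_,
          lipid_path = NA_character_, rgb_path = rp,
          pixel_pitch_um = sp$pixel_pitch_um)
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), na = "")
  jsonlite::write_json(
    list(wells = wells[, c("well_id", "differentiated_fraction")]),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE
  )
  invisible(manifest)
}

#' Generate a sparse field of circular droplets with known geometry
#'
#' A simpler ground-truthed scene for validating droplet sizing: `n`
#' non-overlapping bright discs on a smooth background, no nuclei. Radii
#' are drawn uniformly from `radius_range_um` (or from an explicit vector
#' `radii_um`), placement is rejection-sampled with a margin of one
#' diameter between discs.
#'
#' @param n Number of discs.
#' @param radius_range_um Length-2 range to draw radii from, um.
#' @param radii_um Optional explicit radii (overrides the range).
#' @param width_px,height_px,pixel_pitch_um Field geometry.
#' @param intensity Disc intensity above background.
#' @param background Constant background level.
#' @param noise_sd Additive Gaussian noise SD (disc SNR = intensity /
#'   noise_sd).
#' @param seed Integer seed.
#' @return A list: `image` (a [pixel_grid()]) and `truth` (tibble `row`,
#'   `col`, `radius_um`).
#' @export
generate_droplet_field <- function(n = 20, radius_range_um = c(2, 8),
                                   radii_um = NULL,
                                   width_px = 256, height_px = 256,
                                   pixel_pitch_um = 1, intensity = 150,
                                   background = 20, noise_sd = 3, seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  nr <- height_px; nc <- width_px
  if (is.null(radii_um)) {
    radii_um <- stats::runif(n, radius_range_um[1], radius_range_um[2])
  }
  n <- length(radii_um)
  radii_px <- radii_um / pixel_pitch_um
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    m <- radii_px[i] + 3
    for (attempt in seq_len(10000)) {
      cr <- stats::runif(1, m, nr - m)
      cc <- stats::runif(1, m, nc - m)
      ok <- i == 1 || all(
        sqrt((centers[seq_len(i - 1), 1] - cr)^2 +
             (centers[seq_len(i - 1), 2] - cc)^2) >=
          2 * (radii_px[seq_len(i - 1)] + radii_px[i]))
      if (ok) { centers[i, ] <- c(cr, cc); placed <- TRUE; break }
    }
    if (!placed) {
      stop("density error: could not place all discs; reduce n or radii",
           call. = FALSE)
    }
  }
  canvas <- matrix(background, nr, nc)
  for (i in seq_len(n)) {
    p <- ellipse_patch(nr, nc, centers[i, 1], centers[i, 2],
                       radii_px[i], radii_px[i], 0, intensity)
    if (!is.null(p)) {
      canvas[p$rs, p$cs] <- pmax(canvas[p$rs, p$cs], background + p$values)
    }
  }
  if (noise_sd > 0) canvas <- canvas + stats::rnorm(nr * nc, 0, noise_sd)
  canvas <- matrix(pmin(pmax(round(canvas), 0), 255), nr, nc)
  list(
    image = pixel_grid(canvas, pixel_pitch_um, bit_depth = 8L),
    truth = tibble::tibble(row = centers[, 1], col = centers[, 2],
                           radius_um = radii_um)
  )
}
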