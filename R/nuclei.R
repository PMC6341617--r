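#' Label connected foreground components as candidate nuclei
#'
#' Extracts 8-connected components of a binarised nuclei mask and returns one
#' row per region with its geometry: pixel count, physical area, half-open
#' bounding box, centroid, and aspect ratio. Labels are assigned 1..N in
#' raster order (row-major) of each region's first pixel, so labelling is
#' deterministic and independent of any library ordering. All regions start
#' with status `"kept"`; classification into too-small / too-large /
#' misshapen is a separate, pure annotation step ([filter_regions()]).
#'
#' The aspect ratio is the ratio of the region's principal axis lengths,
#' computed from second central moments with the usual 1/12 per-pixel
#' variance term (each pixel treated as a unit square), so a single pixel
#' has aspect ratio 1 and a 1-by-N line has aspect ratio ~N rather than
#' infinity.
#'
#' @param mask A [binary_mask()] of the nuclei channel.
#' @return A tibble with columns `label`, `area_px`, `area_um2`, `min_row`,
#'   `min_col`, `max_row`, `max_col` (half-open bounds), `centroid_row`,
#'   `centroid_col`, `aspect_ratio`, `status`, and a `pixels` list-column of
#'   two-column (row, col) matrices.
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$values > 0
  if (!any(m)) return(empty_regions())
  lab <- label_matrix_8(m)
  regions_from_labels(lab, mask$pixel_pitch_um)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards through the label adjacency
# graph. Final labels follow raster order of each component's first pixel.
label_matrix_8 <- function(m) {
  lab4 <- EBImage::bwlabel(m)
  lab4 <- matrix(as.integer(round(lab4)), nrow(m), ncol(m))
  k <- max(lab4)
  if (k == 0L) return(lab4)
  nr <- nrow(lab4); nc <- ncol(lab4)
  edges <- NULL
  if (nr > 1L && nc > 1L) {
    a1 <- lab4[-nr, -nc]; b1 <- lab4[-1, -1]      # down-right diagonal
    a2 <- lab4[-1, -nc];  b2 <- lab4[-nr, -1]     # up-right diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::make_empty_graph(n = k, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    map <- as.integer(igraph::components(g)$membership)
  } else {
    map <- seq_len(k)
  }
  lab <- lab4
  lab[lab4 > 0L] <- map[lab4[lab4 > 0L]]
  # renumber by raster order (row-major) of first pixel
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  raster <- (rows - 1L) * nc + cols
  first <- tapply(raster, lab[idx], min)
  order_new <- rank(first, ties.method = "first")
  remap <- integer(max(lab))
  remap[as.integer(names(first))] <- order_new
  lab[idx] <- remap[lab[idx]]
  lab
}

empty_regions <- function() {
  tibble::tibble(
    label = integer(), area_px = integer(), area_um2 = double(),
    min_row = integer(), min_col = integer(), max_row = integer(),
    max_col = integer(), centroid_row = double(), centroid_col = double(),
    aspect_ratio = double(), status = character(), pixels = list()
  )
}

regions_from_labels <- function(lab, pitch) {
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(empty_regions())
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  labv <- lab[idx]
  ord <- order(labv)
  rows <- rows[ord]; cols <- cols[ord]; labv <- labv[ord]
  split_idx <- split(seq_along(labv), labv)
  regs <- purrr::map(split_idx, function(ii) {
    r <- rows[ii]; cc <- cols[ii]
    n <- length(ii)
    mu_r <- mean(r); mu_c <- mean(cc)
    # second central moments with unit-square pixel term
    vr <- sum((r - mu_r)^2) / n + 1 / 12
    vc <- sum((cc - mu_c)^2) / n + 1 / 12
    vrc <- sum((r - mu_r) * (cc - mu_c)) / n
    tr <- vr + vc
    det <- vr * vc - vrc^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc
    l2 <- max(tr / 2 - disc, 1e-12)
    list(
      area_px = n,
      area_um2 = n * pitch^2,
      min_row = min(r), min_col = min(cc),
      max_row = max(r) + 1L, max_col = max(cc) + 1L,
      centroid_row = mu_r, centroid_col = mu_c,
      aspect_ratio = sqrt(l1 / l2),
      pixels = cbind(row = r, col = cc)
    )
  })
  labels <- as.integer(names(split_idx))
  regs <- unname(regs)
  tibble::tibble(
    label = labels,
    area_px = purrr::map_int(regs, "area_px"),
    area_um2 = purrr::map_dbl(regs, "area_um2"),
    min_row = purrr::map_int(regs, "min_row"),
    min_col = purrr::map_int(regs, "min_col"),
    max_row = purrr::map_int(regs, ~ as.integer(.x$max_row)),
    max_col = purrr::map_int(regs, ~ as.integer(.x$max_col)),
    centroid_row = purrr::map_dbl(regs, "centroid_row"),
    centroid_col = purrr::map_dbl(regs, "centroid_col"),
    aspect_ratio = purrr::map_dbl(regs, "aspect_ratio"),
    status = "kept",
    pixels = purrr::map(regs, "pixels")
  )
}

#' Classify regions by size and shape
#'
#' Annotates every region with an exclusion status: `too_small` for debris
#' and pyknotic dead-cell nuclei below the minimum area, `too_large` for
#' fused saturated regions (multilayer clumps whose merged component exceeds
#' the single-nucleus size limit), `misshapen` for regions whose aspect
#' ratio exceeds the bound (dead cells often present highly elongated or
#' crescent-shaped nuclei), and `kept` otherwise. Nothing is deleted — the
#' row order and pixel sets are untouched, and downstream scoring consumes
#' only `status == "kept"` — so exclusion counts per reason remain available
#' for reporting.
#'
#' @param regions A region tibble from [label_components()].
#' @param min_area_um2,max_area_um2 Area bounds in square micrometres
#'   (defaults 20 and 500: mammalian nuclei are roughly 7-12 um across).
#' @param max_aspect_ratio Shape bound (default 3).
#' @return The region tibble with `status` filled in.
#' @export
filter_regions <- function(regions, min_area_um2 = 20, max_area_um2 = 500,
                           max_aspect_ratio = 3) {
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2)) {
    stop("need 0 < min_area_um2 < max_area_um2", call. = FALSE)
  }
  if (max_aspect_ratio < 1) stop("max_aspect_ratio must be >= 1", call. = FALSE)
  dplyr::mutate(
    regions,
    status = dplyr::case_when(
      area_um2 < min_area_um2 ~ "too_small",
      area_um2 > max_area_um2 ~ "too_large",
      aspect_ratio > max_aspect_ratio ~ "misshapen",
      TRUE ~ "kept"
    )
  )
}

#' Split touching nuclei by watershed on the distance transform
#'
#' Applies a watershed to the negated Euclidean distance transform of the
#' foreground, seeded at distance-transform local maxima separated by at
#' least `min_seed_distance_um` (so that texture inside a single convex
#' nucleus does not over-segment it), and inserts one-pixel-wide background
#' cuts along the watershed lines. After the cuts, [label_components()]
#' separates the lobes. When two basins claim adjacent pixels, the cut is
#' taken from the higher-labelled side, a deterministic tie-break.
#'
#' @param mask A [binary_mask()] of the nuclei channel.
#' @param min_seed_distance_um Minimum seed separation in micrometres
#'   (default 6, about one nucleus radius).
#' @return A [binary_mask()] identical to the input except for the cut
#'   pixels removed along region boundaries.
#' @export
split_touching <- function(mask, min_seed_distance_um = 6) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$values > 0
  if (!any(m)) return(mask)
  ext <- max(1L, as.integer(round(min_seed_distance_um / mask$pixel_pitch_um)))
  d <- EBImage::distmap(EBImage::Image(m * 1))
  w <- EBImage::watershed(d, tolerance = 1, ext = ext)
  lab <- matrix(as.integer(round(w)), nrow(m), ncol(m))
  cut <- matrix(FALSE, nrow(m), ncol(m))
  nr <- nrow(lab); nc <- ncol(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    sr <- s[1]; sc <- s[2]
    r_dst <- seq_len(nr); c_dst <- seq_len(nc)
    r_src <- r_dst + sr; c_src <- c_dst + sc
    keep_r <- r_src >= 1 & r_src <= nr
    keep_c <- c_src >= 1 & c_src <= nc
    a <- lab[r_dst[keep_r], c_dst[keep_c], drop = FALSE]
    b <- lab[r_src[keep_r], c_src[keep_c], drop = FALSE]
    hit <- a > 0L & b > 0L & a > b   # cut the larger-labelled side
    sub <- cut[r_dst[keep_r], c_dst[keep_c], drop = FALSE]
    cut[r_dst[keep_r], c_dst[keep_c]] <- sub | hit
  }
  out <- mask$values
  out[cut] <- 0
  binary_mask(out, mask$pixel_pitch_um)
}
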