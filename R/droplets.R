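#' Subtract slowly varying background from the lipid channel
#'
#' Estimates background as a large-window Gaussian smoothing of the image
#' and subtracts it, clamping at zero. With a window several times the
#' largest droplet diameter, droplet-scale structure passes through nearly
#' unchanged while gradients and blotches are removed — the preprocessing
#' needed before radius estimation by the circular Hough transform.
#'
#' @param lipid A [pixel_grid()].
#' @param window_um Smoothing window in micrometres. Should exceed twice
#'   the largest droplet diameter (4x is the pipeline default); pass
#'   `max_droplet_um` to get a warning when it does not.
#' @param max_droplet_um Optional largest expected droplet diameter, um.
#' @return A background-subtracted [pixel_grid()] (same bit depth).
#' @export
subtract_background <- function(lipid, window_um, max_droplet_um = NULL) {
  stopifnot(inherits(lipid, "pixel_grid"))
  if (!is.null(max_droplet_um) && window_um < 2 * max_droplet_um) {
    warning("background window ", window_um, " um is below twice the largest ",
            "droplet diameter; droplets will be attenuated", call. = FALSE)
  }
  z <- kernel_size_px(window_um, lipid$pixel_pitch_um)
  z <- min(z, min(dim(lipid$values)) - (1 - min(dim(lipid$values)) %% 2))
  if (z %% 2 == 0) z <- z - 1
  bg <- gaussian_local_mean(lipid$values, make_gaussian_kernel(z))
  out <- pmax(lipid$values - bg, 0)
  pixel_grid(out, lipid$pixel_pitch_um, bit_depth = lipid$bit_depth)
}

#' Detect circular lipid droplets by circular Hough transform
#'
#' Edge pixels (gradient magnitude above a percentile of the non-zero
#' gradients) vote along their gradient direction at every candidate
#' radius; accumulator peaks above `sensitivity` times the strongest peak,
#' thinned by non-maximum suppression at a minimum centre distance of
#' `r_min_um`, become detections. Votes are normalised by circle
#' circumference so small and large droplets compete fairly.
#'
#' @param lipid_bgsub Background-subtracted lipid channel
#'   ([subtract_background()]).
#' @param r_min_um,r_max_um Radius search range in micrometres; `r_min_um`
#'   must be at least one pixel at the image pitch.
#' @param sensitivity Accumulator threshold as a fraction of the maximum
#'   (default 0.5), in (0, 1].
#' @param edge_percentile Percentile of non-zero gradient magnitudes used
#'   as the edge threshold (default 90).
#' @return A tibble `center_row`, `center_col`, `radius_um`,
#'   `accumulator_score`, sorted by score descending.
#' @export
detect_droplets <- function(lipid_bgsub, r_min_um = 0.5, r_max_um = 10,
                            sensitivity = 0.5, edge_percentile = 90) {
  stopifnot(inherits(lipid_bgsub, "pixel_grid"))
  if (!(r_min_um > 0 && r_min_um < r_max_um)) {
    stop("need 0 < r_min_um < r_max_um", call. = FALSE)
  }
  if (sensitivity <= 0 || sensitivity > 1) {
    stop("`sensitivity` must be in (0, 1]", call. = FALSE)
  }
  pitch <- lipid_bgsub$pixel_pitch_um
  r_min_px <- r_min_um / pitch
  r_max_px <- r_max_um / pitch
  if (r_min_px < 1) {
    stop(sprintf(
      "parameter error: r_min_um = %g um is below one pixel at pitch %g um/pixel",
      r_min_um, pitch), call. = FALSE)
  }
  v <- lipid_bgsub$values
  nr <- nrow(v); nc <- ncol(v)
  empty <- tibble::tibble(center_row = double(), center_col = double(),
                          radius_um = double(), accumulator_score = double())

  # light Gaussian smoothing before differentiation: on hard-edged rims the
  # rasterised normals are quantised, which scatters Hough votes in
  # proportion to the radius; smoothing recovers accurate edge directions
  v <- gaussian_local_mean(v, make_gaussian_kernel(5L))
  # gradients via central differences
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (v[3:nr, ] - v[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (v[, 3:nc] - v[, 1:(nc - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  nz <- mag[mag > 0]
  if (length(nz) == 0) return(empty)
  # percentile threshold with an absolute floor at 3x the median magnitude
  # over all pixels (a robust noise estimate: on noisy images noise fills
  # the frame and sets the median, on clean images the median is ~0), so
  # the sea of noise gradients does not define the edge population
  thr <- max(stats::quantile(nz, edge_percentile / 100), 3 * stats::median(mag))
  edge <- which(mag >= thr & mag > 0)
  if (length(edge) == 0) return(empty)
  er <- (edge - 1L) %% nr + 1L
  ec <- (edge - 1L) %/% nr + 1L
  ur <- gr[edge] / mag[edge]
  uc <- gc[edge] / mag[edge]

  radii_px <- seq(r_min_px, r_max_px, by = min(0.5, (r_max_px - r_min_px) / 2))
  nk <- length(radii_px)
  votes <- array(0, dim = c(nr, nc, nk))
  for (k in seq_len(nk)) {
    r <- radii_px[k]
    # bright discs: the intensity gradient at the rim points toward the
    # centre, so each edge pixel casts a single inward vote at distance r
    cr <- round(er + r * ur)
    cc <- round(ec + r * uc)
    keep <- cr >= 1 & cr <= nr & cc >= 1 & cc <= nc
    if (!any(keep)) next
    idx <- (cc[keep] - 1L) * nr + cr[keep]
    votes[, , k] <- matrix(tabulate(idx, nbins = nr * nc), nr, nc)
  }
  # pool adjacent radius slabs (a rim at a radius between two grid values
  # splits its votes), absorb centre rounding with a 3x3 box sum, then
  # normalise by circumference so radii compete fairly
  acc <- array(0, dim = c(nr, nc, nk))
  for (k in seq_len(nk)) {
    a <- votes[, , k]
    if (k > 1) a <- a + votes[, , k - 1]
    if (k < nk) a <- a + votes[, , k + 1]
    s <- a
    s[1:(nr - 1), ] <- s[1:(nr - 1), ] + a[2:nr, ]
    s[2:nr, ] <- s[2:nr, ] + a[1:(nr - 1), ]
    b <- s
    b[, 1:(nc - 1)] <- b[, 1:(nc - 1)] + s[, 2:nc]
    b[, 2:nc] <- b[, 2:nc] + s[, 1:(nc - 1)]
    acc[, , k] <- b / (2 * pi * radii_px[k])
  }

  peak <- max(acc)
  if (peak <= 0) return(empty)
  cand <- which(acc >= sensitivity * peak, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  scores <- acc[cand]
  ord <- order(scores, cand[, 1], cand[, 2], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  scores <- scores[ord]

  # Non-maximum suppression with an angular-support gate: a genuine circle
  # has edge-strength around most of its rim, whereas rim fragments of a
  # larger circle or chance noise alignments cover only a short arc. A
  # candidate is accepted if at least half of 32 rim samples carry edge
  # strength, and no stronger accepted circle already covers its centre.
  if (nrow(cand) > 2000) { cand <- cand[1:2000, , drop = FALSE]; scores <- scores[1:2000] }
  sel_r <- numeric(0); sel_c <- numeric(0); sel_k <- integer(0); sel_s <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    cr <- cand[i, 1]; cc <- cand[i, 2]
    if (length(sel_r) > 0) {
      d <- sqrt((sel_r - cr)^2 + (sel_c - cc)^2)
      lim <- pmax(radii_px[sel_k], max(r_min_px, 2))
      if (any(d < lim)) next
    }
    if (rim_support(mag, cr, cc, radii_px[cand[i, 3]], thr) < 0.5) next
    sel_r <- c(sel_r, cr); sel_c <- c(sel_c, cc)
    sel_k <- c(sel_k, cand[i, 3]); sel_s <- c(sel_s, scores[i])
  }
  # refine each radius on the rim-gradient profile: the accumulator's radius
  # grid is coarse (0.5 px) and centre rounding biases it low, so take the
  # radius maximising the mean gradient magnitude sampled on the circle
  refined <- vapply(seq_along(sel_r), function(i) {
    refine_radius(mag, sel_r[i], sel_c[i], radii_px[sel_k[i]],
                  r_min_px, r_max_px)
  }, numeric(1))
  tibble::tibble(
    center_row = sel_r, center_col = sel_c,
    radius_um = refined * pitch,
    accumulator_score = sel_s
  ) |>
    dplyr::arrange(dplyr::desc(accumulator_score))
}

# fraction of rim samples whose (bilinear) gradient magnitude reaches the
# edge threshold; rim samples within 1 px tolerance radially
rim_support <- function(mag, cr, cc, r, thr) {
  nr <- nrow(mag); nc <- ncol(mag)
  angles <- seq(0, 2 * pi, length.out = 33)[-33]
  hit <- logical(length(angles))
  for (dr in c(-0.75, 0, 0.75)) {
    rr <- r + dr
    if (rr <= 0.5) next
    rs <- cr + rr * sin(angles)
    cs <- cc + rr * cos(angles)
    ok <- rs >= 1 & rs <= nr - 1 & cs >= 1 & cs <= nc - 1
    if (!any(ok)) next
    r1 <- floor(rs[ok]); c1 <- floor(cs[ok])
    fr <- rs[ok] - r1; fc <- cs[ok] - c1
    v <- (1 - fr) * (1 - fc) * mag[cbind(r1, c1)] +
      fr * (1 - fc) * mag[cbind(r1 + 1, c1)] +
      (1 - fr) * fc * mag[cbind(r1, c1 + 1)] +
      fr * fc * mag[cbind(r1 + 1, c1 + 1)]
    hit[ok] <- hit[ok] | v >= thr * 0.75
  }
  mean(hit)
}

# mean bilinear gradient magnitude on a circle of radius r, maximised over
# r in [r0 - 2, r0 + 2] at 0.25 px steps
refine_radius <- function(mag, cr, cc, r0, r_min_px, r_max_px) {
  nr <- nrow(mag); nc <- ncol(mag)
  angles <- seq(0, 2 * pi, length.out = 33)[-33]
  candidates <- seq(max(r0 - 2, r_min_px), min(r0 + 2, r_max_px), by = 0.25)
  best_r <- r0; best_v <- -Inf
  for (r in candidates) {
    rs <- cr + r * sin(angles)
    cs <- cc + r * cos(angles)
    ok <- rs >= 1 & rs <= nr - 1 & cs >= 1 & cs <= nc - 1
    if (!any(ok)) next
    r1 <- floor(rs[ok]); c1 <- floor(cs[ok])
    fr <- rs[ok] - r1; fc <- cs[ok] - c1
    v <- (1 - fr) * (1 - fc) * mag[cbind(r1, c1)] +
      fr * (1 - fc) * mag[cbind(r1 + 1, c1)] +
      (1 - fr) * fc * mag[cbind(r1, c1 + 1)] +
      fr * fc * mag[cbind(r1 + 1, c1 + 1)]
    val <- mean(v)
    if (val > best_v) { best_v <- val; best_r <- r }
  }
  best_r
}

#' Summarise droplet radii
#'
#' @param detections Tibble from [detect_droplets()].
#' @param bins Histogram bin count (default 20).
#' @return A list of class `droplet_summary`: `n_droplets`,
#'   `mean_radius_um` (`NA` when empty), `radius_histogram` (breaks +
#'   counts).
#' @export
summarize_radii <- function(detections, bins = 20) {
  n <- nrow(detections)
  if (n == 0) {
    return(structure(list(n_droplets = 0L, mean_radius_um = NA_real_,
                          radius_histogram = list(breaks = numeric(),
                                                  counts = integer())),
                     class = "droplet_summary"))
  }
  rng <- range(detections$radius_um)
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = bins + 1)
  counts <- as.integer(graphics::hist(detections$radius_um, breaks = breaks,
                                      plot = FALSE)$counts)
  structure(list(n_droplets = n, mean_radius_um = mean(detections$radius_um),
                 radius_histogram = list(breaks = breaks, counts = counts)),
            class = "droplet_summary")
}

#' @export
print.droplet_summary <- function(x, ...) {
  if (x$n_droplets == 0) {
    cat("<droplet_summary> no droplets detected\n")
  } else {
    cat(sprintf("<droplet_summary> %d droplets, mean radius %.2f um\n",
                x$n_droplets, x$mean_radius_um))
  }
  invisible(x)
}
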