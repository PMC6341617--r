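mask_of <- function(m) binary_mask(ifelse(m, 255, 0), 1)

test_that("connected components: empty, separate, and diagonal-touching regions", {
  expect_equal(nrow(label_components(mask_of(matrix(FALSE, 8, 8)))), 0)

  m <- matrix(FALSE, 30, 30)
  m[disc_mask(30, 30, 8, 8, 4)] <- TRUE
  m[disc_mask(30, 30, 22, 22, 4)] <- TRUE
  regs <- label_components(mask_of(m))
  expect_equal(nrow(regs), 2)
  all_px <- do.call(rbind, regs$pixels)
  expect_equal(nrow(all_px), sum(m))
  expect_equal(anyDuplicated(all_px), 0)

  # two blocks touching only at one diagonal pixel pair: one region under
  # 8-connectivity
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE
  m[5:7, 5:7] <- TRUE
  expect_equal(nrow(label_components(mask_of(m))), 1)
  expect_equal(nrow(label_components(mask_of(m))), oracle_n_components_8(m))
})

test_that("labelling agrees with a flood-fill oracle on random masks", {
  set.seed(99)
  for (rep in 1:6) {
    m <- matrix(runif(20 * 20) < 0.35, 20, 20)
    regs <- label_components(mask_of(m))
    expect_equal(nrow(regs), oracle_n_components_8(m))
    expect_equal(sum(regs$area_px), sum(m))
  }
})

test_that("region geometry: bbox, centroid, aspect ratio of an ideal line", {
  m <- matrix(FALSE, 10, 40)
  m[5, 6:35] <- TRUE   # 1 x 30 horizontal line
  regs <- label_components(mask_of(m))
  expect_equal(nrow(regs), 1)
  expect_equal(regs$area_px, 30L)
  expect_equal(regs$min_row, 5L); expect_equal(regs$max_row, 6L)
  expect_equal(regs$min_col, 6L); expect_equal(regs$max_col, 36L)
  expect_equal(regs$centroid_row, 5)
  expect_equal(regs$centroid_col, mean(6:35))
  # second-moment axes with the unit-pixel term: major^2 = (n^2-1)/12 + 1/12,
  # minor^2 = 1/12, so aspect = sqrt(n^2) = n
  expect_equal(regs$aspect_ratio, 30, tolerance = 1e-9)
  # a single pixel is perfectly round
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(label_components(mask_of(m1))$aspect_ratio, 1, tolerance = 1e-12)
})

test_that("region filters annotate without deleting", {
  m <- matrix(FALSE, 60, 60)
  m[2:3, 2:3] <- TRUE                       # 4 px: too small at min 20 um2
  m[disc_mask(60, 60, 20, 20, 5)] <- TRUE   # kept
  m[40, 10:39] <- TRUE                      # line: misshapen
  regs <- label_components(mask_of(m))
  out <- filter_regions(regs, min_area_um2 = 20, max_area_um2 = 500,
                        max_aspect_ratio = 3)
  expect_equal(sort(out$status), sort(c("too_small", "kept", "misshapen")))
  # pure annotation: pixels and order untouched
  expect_identical(out$pixels, regs$pixels)
  expect_identical(out$label, regs$label)

  # a giant fused region exceeds the single-nucleus maximum
  m2 <- matrix(FALSE, 80, 80)
  m2[disc_mask(80, 80, 40, 40, 25)] <- TRUE  # ~1960 um2 >> 500
  out2 <- filter_regions(label_components(mask_of(m2)))
  expect_equal(out2$status, "too_large")

  expect_error(filter_regions(regs, min_area_um2 = 30, max_area_um2 = 10),
               "min_area_um2")
})

test_that("watershed splitting: single discs pass through, fused pairs split", {
  # single convex disc: unchanged
  m <- matrix(FALSE, 40, 40)
  m[disc_mask(40, 40, 20, 20, 9)] <- TRUE
  sp <- split_touching(mask_of(m), min_seed_distance_um = 6)
  expect_identical(sp$values, mask_of(m)$values)

  # two equal discs overlapping ~30% of radius: exactly 2 near-equal lobes
  m2 <- matrix(FALSE, 60, 60)
  m2[disc_mask(60, 60, 30, 22, 10)] <- TRUE
  m2[disc_mask(60, 60, 30, 38, 10)] <- TRUE
  sp2 <- split_touching(mask_of(m2), 6)
  regs <- label_components(sp2)
  expect_equal(nrow(regs), 2)
  expect_lt(abs(diff(regs$area_px)) / max(regs$area_px), 0.15)

  # dumbbell joined by a thin bridge: cut lands on the bridge
  m3 <- matrix(FALSE, 50, 70)
  m3[disc_mask(50, 70, 25, 18, 8)] <- TRUE
  m3[disc_mask(50, 70, 25, 52, 8)] <- TRUE
  m3[25, 18:52] <- TRUE
  sp3 <- split_touching(mask_of(m3), 6)
  expect_equal(nrow(label_components(sp3)), 2)
})

test_that("re-splitting an already split mask keeps the component count", {
  m <- matrix(FALSE, 60, 60)
  m[disc_mask(60, 60, 30, 22, 10)] <- TRUE
  m[disc_mask(60, 60, 30, 38, 10)] <- TRUE
  once <- split_touching(mask_of(m), 6)
  twice <- split_touching(once, 6)
  expect_equal(nrow(label_components(twice)), nrow(label_components(once)))
})

test_that("kept-nucleus count tracks ground truth on a dense synthetic field", {
  sc <- generate_scene(scene_spec(width_px = 500, height_px = 500,
                                  n_nuclei = 300, pixel_pitch_um = 0.65,
                                  nucleus_radius_um = c(4, 0.5),
                                  differentiated_fraction = 0, seed = 21))
  res <- analyze_field(sc$image, scene_config())
  n_true <- nrow(sc$truth$nuclei)
  expect_lte(abs(nrow(res$scores) - n_true) / n_true, 0.05)
})

test_that("planted dead cells are never among kept regions", {
  for (sd in 1:3) {
    sc <- generate_scene(scene_spec(width_px = 320, height_px = 320,
                                    n_nuclei = 40, n_dead_cells = 8,
                                    differentiated_fraction = 0, seed = sd))
    res <- analyze_field(sc$image, scene_config())
    kept <- dplyr::filter(res$regions, status == "kept")
    for (i in seq_len(nrow(sc$truth$dead_cells))) {
      d <- sqrt((kept$centroid_row - sc$truth$dead_cells$row[i])^2 +
                (kept$centroid_col - sc$truth$dead_cells$col[i])^2)
      expect_true(all(d > 4), label = sprintf("dead cell %d seed %d excluded", i, sd))
    }
  }
})
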