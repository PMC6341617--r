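region_row <- function(min_row, min_col, max_row, max_col, label = 1L) {
  tibble::tibble(
    label = label, area_px = 1L, area_um2 = 1,
    min_row = min_row, min_col = min_col, max_row = max_row, max_col = max_col,
    centroid_row = (min_row + max_row - 1) / 2,
    centroid_col = (min_col + max_col - 1) / 2,
    aspect_ratio = 1, status = "kept",
    pixels = list(cbind(row = min_row, col = min_col))
  )
}

test_that("lipid score arithmetic matches hand-computed values", {
  # 10x10 search region: 25 foreground px of mean intensity 200
  lip <- matrix(0, 10, 10)
  msk <- matrix(0, 10, 10)
  msk[1:5, 1:5] <- 255
  lip[1:5, 1:5] <- 200
  reg <- region_row(1L, 1L, 11L, 11L)   # bbox covers the image, radius 0
  sc <- score_nucleus(reg, pixel_grid(lip, 1), binary_mask(msk, 1),
                      search_radius_um = 0)
  expect_equal(sc$p_t, 0.25)
  expect_equal(sc$i_s, 200)
  expect_equal(sc$s, 50)

  # brute-force pixel loop oracle on a non-uniform pattern
  set.seed(12)
  lip2 <- matrix(sample(0:255, 100, TRUE), 10, 10)
  msk2 <- matrix(ifelse(runif(100) < 0.4, 255, 0), 10, 10)
  sc2 <- score_nucleus(reg, pixel_grid(lip2, 1), binary_mask(msk2, 1), 0)
  fg <- which(msk2 == 255)
  expect_equal(sc2$p_t, length(fg) / 100)
  expect_equal(sc2$i_s, mean(lip2[fg]))
  expect_equal(sc2$s, sc2$p_t * sc2$i_s)

  # zero foreground -> all zeros
  sc3 <- score_nucleus(reg, pixel_grid(lip2, 1),
                       binary_mask(matrix(0, 10, 10), 1), 0)
  expect_equal(c(sc3$p_t, sc3$i_s, sc3$s), c(0, 0, 0))

  # fully foreground uniform intensity v -> p_t = 1, s = v
  sc4 <- score_nucleus(reg, pixel_grid(matrix(77, 10, 10), 1),
                       binary_mask(matrix(255, 10, 10), 1), 0)
  expect_equal(c(sc4$p_t, sc4$i_s, sc4$s), c(1, 77, 77))
})

test_that("search region is the bounding box dilated by the physical radius", {
  lip <- matrix(0, 20, 20)
  msk <- matrix(0, 20, 20)
  msk[5, 14] <- 255   # 3 px right of the bbox edge
  lip[5, 14] <- 100
  reg <- region_row(4L, 4L, 12L, 12L)  # bbox rows 4..11, cols 4..11
  # radius 2 um at pitch 1: droplet at col 14 is outside (cols 2..13)
  s2 <- score_nucleus(reg, pixel_grid(lip, 1), binary_mask(msk, 1), 2)
  expect_equal(s2$s, 0)
  # radius 3 um: region cols 1..14 includes it
  s3 <- score_nucleus(reg, pixel_grid(lip, 1), binary_mask(msk, 1), 3)
  expect_gt(s3$s, 0)
  expect_equal(s3$i_s, 100)
})

test_that("gating is strictly greater-than and order preserving", {
  scores <- tibble::tibble(
    nucleus_label = 1:3, centroid_row = 0, centroid_col = 0,
    p_t = 1, i_s = c(0, 5, 10), s = c(0, 5, 10), differentiated = NA
  )
  g <- gate_scores(scores, 5)
  expect_identical(g$differentiated, c(FALSE, FALSE, TRUE))
  expect_identical(g$nucleus_label, 1:3)
  g0 <- gate_scores(dplyr::mutate(scores, s = 0), 1)
  expect_equal(sum(g0$differentiated), 0)
  expect_error(gate_scores(scores, -1), "non-negative")
})

test_that("well aggregation pools fields without weighting them", {
  mk <- function(s, diff) tibble::tibble(
    nucleus_label = seq_along(s), centroid_row = 0, centroid_col = 0,
    p_t = 0.5, i_s = 2 * s, s = s, differentiated = diff
  )
  f1 <- mk(rep(1, 50), c(rep(TRUE, 10), rep(FALSE, 40)))
  f2 <- mk(rep(3, 50), c(rep(TRUE, 20), rep(FALSE, 30)))
  w <- aggregate_well("B02", list(f1, f2), gate_threshold = 0.5)
  expect_equal(w$n_nuclei, 100)
  expect_equal(w$adipogenic_score, 30)       # (10+20)/100, not mean(20%, 40%)
  expect_equal(w$mean_lipid_score, 2)
  expect_equal(sum(w$histogram$counts), 100)
  # pooling identity: one concatenated field gives the same result
  w2 <- aggregate_well("B02", dplyr::bind_rows(f1, f2), gate_threshold = 0.5)
  expect_equal(w2$adipogenic_score, w$adipogenic_score)
  expect_equal(w2$mean_lipid_score, w$mean_lipid_score)
  expect_equal(w2$histogram, w$histogram)

  # single field, 4 nuclei, 1 differentiated
  w3 <- aggregate_well("A01", mk(1:4, c(TRUE, FALSE, FALSE, FALSE)))
  expect_equal(w3$adipogenic_score, 25)

  # all-equal scores concentrate in one bin at the mean
  w4 <- aggregate_well("A02", mk(rep(7, 20), rep(FALSE, 20)))
  expect_equal(w4$mean_lipid_score, 7)
  expect_equal(sum(w4$histogram$counts > 0), 1)

  # an empty well is invalid, score reported missing rather than zero
  w5 <- aggregate_well("H12", mk(numeric(0), logical(0)))
  expect_false(w5$valid)
  expect_true(is.na(w5$adipogenic_score))
})

test_that("tidy and glance expose per-nucleus and per-well views", {
  f <- tibble::tibble(
    nucleus_label = 1:4, centroid_row = 0, centroid_col = 0,
    p_t = 0.1, i_s = 10, s = c(0, 1, 2, 3), differentiated = c(F, F, T, T)
  )
  w <- aggregate_well("C03", f, gate_threshold = 1.5)
  td <- generics::tidy(w)
  expect_equal(nrow(td), 4)
  expect_true(all(td$well_id == "C03"))
  gl <- generics::glance(w)
  expect_equal(gl$adipogenic_score, 50)
  expect_equal(gl$n_nuclei, 4L)
})

test_that("control comparison ranks wells by score delta", {
  mk_well <- function(id, score) {
    structure(list(well_id = id, scores = NULL, n_nuclei = 10L,
                   adipogenic_score = score, mean_lipid_score = 1,
                   histogram = NULL, gate_threshold = 1, valid = TRUE),
              class = "well_result")
  }
  wells <- list(mk_well("D01", 64.99), mk_well("C01", 20), mk_well("C02", 40),
                mk_well("D02", 30), mk_well("D03", 10))
  tbl <- compare_to_control(wells, c("C01", "C02"))
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$well_id, c("D01", "D02", "D03"))   # sorted descending
  expect_equal(tbl$delta, c(34.99, 0, -20))
  expect_error(compare_to_control(wells, "Z99"), "control")
})

test_that("scores scale monotonically with lipid intensity at fixed geometry", {
  set.seed(8)
  lip <- matrix(sample(10:100, 400, TRUE), 20, 20)
  msk <- matrix(ifelse(runif(400) < 0.3, 255, 0), 20, 20)
  reg <- region_row(5L, 5L, 15L, 15L)
  base <- score_nucleus(reg, pixel_grid(lip, 1), binary_mask(msk, 1), 3)
  up <- score_nucleus(reg, pixel_grid(round(lip * 1.5), 1, bit_depth = 8),
                      binary_mask(msk, 1), 3)
  expect_equal(up$p_t, base$p_t)
  expect_gte(up$i_s, base$i_s)
  expect_gte(up$s, base$s)

  # adipogenic score is non-increasing in the gate threshold
  s_vals <- runif(200, 0, 100)
  scores <- tibble::tibble(nucleus_label = 1:200, centroid_row = 0,
                           centroid_col = 0, p_t = 1, i_s = s_vals,
                           s = s_vals, differentiated = NA)
  gates <- seq(0, 110, by = 10)
  rates <- vapply(gates, function(g) {
    mean(gate_scores(scores, g)$differentiated) * 100
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})
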