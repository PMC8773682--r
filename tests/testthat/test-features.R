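make_field <- function(ch1, ch2, ann = NULL) {
  ch <- list(NUCLEUS_ALL = nucleus_channel(ch1),
             IMPERMEABLE_DNA = dna_dye_channel(ch2))
  if (!is.null(ann)) {
    ch$ANNEXIN <- channel_image(ann, 16L, "ANNEXIN", PSZ)
  }
  field_image(ch, well_id = "A01")
}

test_that("target mask with zero dilation is the nuclear mask", {
  px <- disc_matrix(64, 64, cbind(32, 32), 8, values = 5000)
  mask <- labeled_mask(matrix(as.integer(px > 0), 64, 64))
  tg <- build_target_mask(mask, target_mask_params(dilation_um = 0), PSZ)
  expect_identical(tg$labels, mask$labels)
})

test_that("single-object dilation matches the Euclidean disc area", {
  px <- disc_matrix(96, 96, cbind(48, 48), 10, values = 5000)
  mask <- labeled_mask(matrix(as.integer(px > 0), 96, 96))
  tg <- build_target_mask(mask, target_mask_params(dilation_um = 5 * PSZ),
                          PSZ)
  area <- sum(tg$labels == 1L)
  expect_equal(area, pi * 15^2, tolerance = 0.02)
  # brute-force Euclidean dilation: pixels within 5 px of any disc pixel
  obj <- which(px > 0, arr.ind = TRUE)
  inside <- matrix(FALSE, 96, 96)
  for (r in 1:96) for (c in 1:96) {
    inside[r, c] <- min((obj[, 1] - r)^2 + (obj[, 2] - c)^2) <= 25
  }
  expect_identical(unname(tg$labels == 1L), unname(inside))
})

test_that("contested dilation pixels partition between adjacent objects", {
  labs <- matrix(0L, 64, 64)
  labs[disc_matrix(64, 64, cbind(32, 24), 5) > 0] <- 1L
  labs[disc_matrix(64, 64, cbind(32, 44), 5) > 0] <- 2L
  mask <- labeled_mask(labs)
  tg <- build_target_mask(mask, target_mask_params(dilation_um = 8 * PSZ),
                          PSZ)
  # every contested pixel got exactly one owner; both regions grew
  expect_true(all(tg$labels %in% 0:2))
  expect_gt(sum(tg$labels == 1L), sum(labs == 1L))
  expect_gt(sum(tg$labels == 2L), sum(labs == 2L))
  # pixels on each side of the midline belong to the nearer centroid
  expect_equal(unique(tg$labels[32, 20:30][tg$labels[32, 20:30] > 0]), 1L)
  expect_equal(unique(tg$labels[32, 38:48][tg$labels[32, 38:48] > 0]), 2L)
})

test_that("measurements recover constructed areas and intensities", {
  # nucleus disc r=5 inside a ch2 cloud r=11, cloud within target region
  ch1 <- disc_matrix(96, 96, cbind(48, 48), 5, values = 8000)
  cloud <- disc_matrix(96, 96, cbind(48, 48), 11, values = 600)
  fld <- make_field(ch1, cloud)
  nuclei <- labeled_mask(matrix(as.integer(ch1 > 0), 96, 96))
  tg <- build_target_mask(nuclei, target_mask_params(dilation_um = 8), PSZ)
  fg <- identify_ch2_foreground(fld$channels$IMPERMEABLE_DNA, 500)
  rec <- measure_objects(fld, nuclei, tg, fg)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$target_area_ch2_um2, sum(cloud > 0) * PSZ^2)
  expect_equal(rec$area_ch1_um2, sum(ch1 > 0) * PSZ^2)

  # no ch2 signal -> zero target area; uniform ch2 -> exact mean
  fld0 <- make_field(ch1, matrix(0, 96, 96))
  rec0 <- measure_objects(fld0, nuclei, tg,
                          identify_ch2_foreground(fld0$channels$IMPERMEABLE_DNA, 500))
  expect_equal(rec0$target_area_ch2_um2, 0)
  expect_equal(rec0$avg_intensity_ch2, 0)
  fldU <- make_field(ch1, matrix(500, 96, 96))
  recU <- measure_objects(fldU, nuclei, tg,
                          identify_ch2_foreground(fldU$channels$IMPERMEABLE_DNA, 100))
  expect_equal(recU$avg_intensity_ch2, 500)
})

test_that("record count tracks the number of nuclei, not channel content", {
  ch1 <- disc_matrix(96, 96, cbind(c(25, 48, 70), c(30, 60, 25)), 5,
                     values = 8000)
  nuclei <- identify_primary_objects(
    nucleus_channel(ch1),
    segmentation_params(threshold_method = "FIXED", fixed_threshold = 4000,
                        min_object_area_um2 = 5)
  )
  fld <- make_field(ch1, matrix(0, 96, 96))
  tg <- build_target_mask(nuclei, target_mask_params(), PSZ)
  rec <- measure_objects(fld, nuclei, tg, matrix(FALSE, 96, 96))
  expect_equal(nrow(rec), nuclei$n_objects)
  expect_equal(nrow(rec), 3L)
})

test_that("summed target areas never exceed the ch2 foreground area", {
  set.seed(21)
  fx <- random_disc_image(5, size = 128)
  ch1 <- fx$pixels
  ch2 <- disc_matrix(128, 128, fx$centers, fx$radii + 6, values = 700)
  fld <- make_field(ch1, ch2)
  nuclei <- identify_primary_objects(
    nucleus_channel(ch1),
    segmentation_params(threshold_method = "FIXED", fixed_threshold = 2500,
                        min_object_area_um2 = 5)
  )
  tg <- build_target_mask(nuclei, target_mask_params(), PSZ)
  fg <- identify_ch2_foreground(fld$channels$IMPERMEABLE_DNA, 500)
  rec <- measure_objects(fld, nuclei, tg, fg)
  expect_lte(sum(rec$target_area_ch2_um2), sum(fg) * PSZ^2 + 1e-9)
  for (i in seq_len(nrow(rec))) {
    expect_lte(rec$target_area_ch2_um2[i], sum(tg$labels == i) * PSZ^2)
  }
})

test_that("features are invariant under whole-field translation", {
  base_ch1 <- disc_matrix(128, 128, cbind(c(40, 80), c(45, 85)), c(6, 8),
                          values = 8000)
  base_ch2 <- disc_matrix(128, 128, cbind(c(40, 80), c(45, 85)), c(10, 12),
                          values = 700)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  run <- function(ch1, ch2) {
    fld <- make_field(ch1, ch2)
    nuclei <- identify_primary_objects(
      nucleus_channel(ch1),
      segmentation_params(threshold_method = "FIXED", fixed_threshold = 4000,
                          min_object_area_um2 = 5)
    )
    tg <- build_target_mask(nuclei, target_mask_params(), PSZ)
    fg <- identify_ch2_foreground(fld$channels$IMPERMEABLE_DNA, 500)
    measure_objects(fld, nuclei, tg, fg)
  }
  a <- run(base_ch1, base_ch2)
  b <- run(shift(base_ch1, 7, 13), shift(base_ch2, 7, 13))
  cols <- c("area_ch1_um2", "target_area_ch2_um2", "avg_intensity_ch2",
            "avg_intensity_ch1")
  expect_equal(a[, cols], b[, cols], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(b$centroid_row - a$centroid_row, c(7, 7))
  expect_equal(b$centroid_col - a$centroid_col, c(13, 13))
})

test_that("annexin descriptors separate uniform, surface and punctate", {
  nuc_px <- disc_matrix(72, 72, cbind(36, 36), 6, values = 8000)
  nuclei <- labeled_mask(matrix(as.integer(nuc_px > 0), 72, 72))
  tg <- build_target_mask(nuclei, target_mask_params(), PSZ)
  ch2 <- matrix(0, 72, 72)

  # uniform annexin: ring ratio ~ 1, cv ~ 0
  fldU <- make_field(nuc_px, ch2, ann = matrix(500, 72, 72))
  dU <- annexin_descriptors(fldU, nuclei, tg)
  expect_equal(dU$ring_ratio, 1, tolerance = 0.05)
  expect_lt(dU$cv, 0.05)

  # annexin confined to a 2-px band just outside the nucleus
  rows <- matrix(seq_len(72), 72, 72)
  cols <- matrix(seq_len(72), 72, 72, byrow = TRUE)
  d <- sqrt((rows - 36)^2 + (cols - 36)^2)
  ring <- matrix(0, 72, 72); ring[d > 6 & d <= 8] <- 1000
  dR <- annexin_descriptors(make_field(nuc_px, ch2, ann = ring), nuclei, tg)
  expect_gt(dR$ring_ratio, 5)

  # punctate annexin: bright speckles on dark surroundings
  pts <- disc_matrix(72, 72, cbind(c(30, 42, 36, 32, 41), c(30, 42, 44, 40, 31)),
                     1.2, values = 1000)
  dP <- annexin_descriptors(make_field(nuc_px, ch2, ann = pts), nuclei, tg)
  expect_gt(dP$cv, 1)
  # closed-form CV of the two-valued distribution over the target region
  vals <- pts[tg$labels == 1L]
  p <- mean(vals > 0)
  expect_equal(dP$cv, sqrt((1 - p) / p), tolerance = 0.1)

  # missing channel errors
  fld2 <- make_field(nuc_px, ch2)
  expect_error(annexin_descriptors(fld2, nuclei, tg),
               class = "netscan_config_error")
})
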