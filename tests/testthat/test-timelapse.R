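frame_rec <- function(t, rows, cols, area = 10, intensity = 100) {
  n <- length(rows)
  data.frame(
    object_id = seq_len(n),
    well_id = rep("A01", n), field_index = rep(1L, n),
    time_point_min = rep(t, n),
    centroid_row = rows, centroid_col = cols,
    area_ch1_um2 = rep(40, n),
    target_area_ch2_um2 = rep(area, length.out = n),
    avg_intensity_ch2 = rep(intensity, length.out = n),
    avg_intensity_ch1 = rep(1000, n),
    annexin_ring_ratio = rep(NA_real_, n), annexin_cv = rep(NA_real_, n),
    border = rep(FALSE, n), stringsAsFactors = FALSE
  )
}

test_that("a stationary object yields one two-entry track", {
  frames <- list(frame_rec(0, 50, 50), frame_rec(15, 50.5, 50.2))
  tr <- link_frames(frames, pixel_size_um = PSZ)
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]$entries), 2L)
  expect_equal(sum(!is.na(tr[[1]]$entries$object_id)), 2L)
})

test_that("moves beyond max displacement break tracks", {
  # two objects would have to travel ~50 um to be re-linked
  d_px <- 50 / PSZ
  frames <- list(
    frame_rec(0, c(20, 20 + d_px), c(20, 20)),
    frame_rec(15, c(20 + d_px, 20), c(20 + d_px, 20 + d_px))
  )
  tr <- link_frames(frames, pixel_size_um = PSZ, max_displacement_um = 10)
  expect_length(tr, 4L)  # both die, both reborn
})

test_that("greedy linking preserves identity and equals optimal assignment", {
  # A moves 3 um, B moves 4 um, no conflicts
  a0 <- c(20, 20); b0 <- c(60, 60)
  a1 <- a0 + c(3 / PSZ, 0); b1 <- b0 + c(0, 4 / PSZ)
  frames <- list(
    frame_rec(0, c(a0[1], b0[1]), c(a0[2], b0[2])),
    frame_rec(15, c(a1[1], b1[1]), c(a1[2], b1[2]))
  )
  tr <- link_frames(frames, pixel_size_um = PSZ)
  expect_length(tr, 2L)
  # identity: track starting at A ends at A's new position
  starts <- vapply(tr, function(t) t$entries$centroid_row[1], numeric(1))
  ends <- vapply(tr, function(t) rev(t$entries$centroid_row)[1], numeric(1))
  expect_equal(ends[order(starts)], c(a1[1], b1[1]))
  # oracle: brute-force minimal-cost assignment picks the same pairing
  d <- sqrt(outer(c(a0[1], b0[1]), c(a1[1], b1[1]), "-")^2 +
              outer(c(a0[2], b0[2]), c(a1[2], b1[2]), "-")^2) * PSZ
  best <- brute_assignment(d, 10)
  expect_equal(best[, 1], best[, 2])  # A->A, B->B
})

test_that("gaps up to max_gap are bridged", {
  frames <- list(
    frame_rec(0, 50, 50),
    frame_rec(15, numeric(0), numeric(0)),  # dropped frame
    frame_rec(30, 50.4, 50.1)
  )
  tr <- link_frames(frames, pixel_size_um = PSZ, max_gap = 1L)
  expect_length(tr, 1L)
  e <- tr[[1]]$entries
  expect_equal(nrow(e), 3L)
  expect_true(is.na(e$object_id[2]))
  # with max_gap = 0 the track breaks instead
  tr0 <- link_frames(frames, pixel_size_um = PSZ, max_gap = 0L)
  expect_length(tr0, 2L)
})

test_that("out-of-order frames are rejected", {
  frames <- list(frame_rec(30, 50, 50), frame_rec(15, 50, 50))
  expect_error(link_frames(frames), class = "netscan_input_error")
})

test_that("trajectory fates follow the permeability/decondensation rules", {
  refs <- reference_levels(intensity_ref = 400, area_ref_um2 = 100)
  mk_track <- function(times, areas, ints) {
    structure(list(
      track_id = 1L,
      entries = data.frame(
        frame = seq_along(times), time_point_min = times,
        object_id = seq_along(times), centroid_row = 0, centroid_col = 0,
        target_area_ch2_um2 = areas, avg_intensity_ch2 = ints
      )
    ), class = "cell_track")
  }
  t <- seq(0, 180, 15)
  # never permeable -> LIVE
  live <- mk_track(t, rep(10, 13), rep(100, 13))
  expect_equal(classify_trajectory(live, refs)$fate, "LIVE")
  # permeable at 30 min, area stays at 0.5 A* through 180 -> NECROSIS
  nec <- mk_track(t, rep(50, 13), ifelse(t >= 30, 800, 100))
  out <- classify_trajectory(nec, refs)
  expect_equal(out$fate, "NECROSIS")
  expect_equal(out$first_permeable_min, 30)
  # permeable at 90, area rises to 3 A* by 150 -> NETOSIS
  area_net <- ifelse(t < 90, 20, pmin(300, 20 + (t - 90) * 5))
  net <- mk_track(t, area_net, ifelse(t >= 90, 900, 100))
  expect_equal(classify_trajectory(net, refs)$fate, "NETOSIS")
  # permeable at 165, track ends at 180, small area -> AMBIGUOUS
  amb <- mk_track(t, rep(50, 13), ifelse(t >= 165, 800, 100))
  expect_equal(classify_trajectory(amb, refs)$fate, "AMBIGUOUS")
  # too-short tracks are rejected
  short <- mk_track(c(0, 15), c(10, 10), c(100, 100))
  expect_error(classify_trajectory(short, refs),
               class = "netscan_track_error")
})

test_that("every detection lands in exactly one track", {
  set.seed(33)
  n <- 8
  rows <- runif(n, 20, 100); cols <- runif(n, 20, 100)
  frames <- lapply(seq(0, 60, 15), function(t) {
    frame_rec(t, rows + rnorm(n, 0, 0.5), cols + rnorm(n, 0, 0.5))
  })
  tr <- link_frames(frames, pixel_size_um = PSZ)
  det_total <- sum(vapply(frames, nrow, integer(1)))
  det_in_tracks <- sum(vapply(tr, function(t) {
    sum(!is.na(t$entries$object_id))
  }, integer(1)))
  expect_equal(det_in_tracks, det_total)
})
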