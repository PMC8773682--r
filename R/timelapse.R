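# Time-lapse tracking and death-trajectory classification.
#
# Frames 15 min apart at low neutrophil density justify greedy
# nearest-pair linking: candidate (track, detection) pairs are sorted by
# distance and assigned greedily, with moves beyond max_displacement_um
# forbidden and deterministic tie-breaks. Trajectory fates follow the
# permeability/decondensation sequence: necrosis shows early dye entry
# with a nucleus that stays condensed through prolonged follow-up, while
# NETosis shows dye entry followed by progressive growth of the dye-
# positive area. Permeable tracks without enough follow-up to rule out
# later decondensation are AMBIGUOUS, not necrotic.

#' Link per-frame detections into tracks
#'
#' @param frame_records list of per-frame data.frames (output of
#'   [measure_objects]) in strictly increasing time order; each needs
#'   `time_point_min`, `object_id`, `centroid_row`, `centroid_col`,
#'   `target_area_ch2_um2`, `avg_intensity_ch2`.
#' @param pixel_size_um physical pixel size used to express displacements
#'   in um.
#' @param max_displacement_um maximum allowed move between consecutive
#'   frames (scaled up proportionally when bridging a gap). Default 10.
#' @param max_gap maximum number of consecutive missed frames inside a
#'   track. Default 1.
#' @return list of `track` objects: each has `track_id` and an `entries`
#'   data.frame with one row per frame from first to last detection
#'   (missing frames have `object_id = NA`).
#' @export
link_frames <- function(frame_records, pixel_size_um = 0.65,
                        max_displacement_um = 10, max_gap = 1L) {
  if (length(frame_records) < 2L) {
    ns_stop("link_frames needs at least two frames", "netscan_input_error")
  }
  times <- vapply(frame_records, function(f) {
    if (nrow(f)) f$time_point_min[1] else NA_real_
  }, numeric(1))
  # frames may legitimately be empty; fill missing times by position
  known <- which(!is.na(times))
  if (any(diff(times[known]) <= 0)) {
    ns_stop("frames must be in strictly increasing time order",
            "netscan_input_error")
  }
  n_frames <- length(frame_records)
  tracks <- list()        # finished + active; entries accumulated
  active <- integer(0)    # indices into tracks that may still be extended
  last_seen <- integer(0) # frame index of last detection per active track
  last_pos <- NULL        # matrix of (row, col) px per active track

  new_track <- function(rec_row, frame_i) {
    id <- length(tracks) + 1L
    tracks[[id]] <<- list(
      track_id = id,
      frames = frame_i,
      rows = rec_row$centroid_row,
      cols = rec_row$centroid_col,
      object_id = rec_row$object_id,
      time = rec_row$time_point_min,
      area = rec_row$target_area_ch2_um2,
      intensity = rec_row$avg_intensity_ch2
    )
    id
  }

  f1 <- frame_records[[1]]
  for (j in seq_len(nrow(f1))) {
    id <- new_track(f1[j, ], 1L)
    active <- c(active, id)
    last_seen <- c(last_seen, 1L)
  }

  for (fi in 2:n_frames) {
    rec <- frame_records[[fi]]
    # retire tracks that exceeded the allowed gap
    keep <- (fi - last_seen) <= (max_gap + 1L)
    active <- active[keep]; last_seen <- last_seen[keep]
    assigned_track <- rep(FALSE, length(active))
    assigned_det <- rep(FALSE, nrow(rec))
    if (length(active) && nrow(rec)) {
      tr_r <- vapply(tracks[active], function(t) t$rows[length(t$rows)],
                     numeric(1))
      tr_c <- vapply(tracks[active], function(t) t$cols[length(t$cols)],
                     numeric(1))
      gaps <- fi - last_seen  # 1 for consecutive frames
      d_um <- outer(tr_r, rec$centroid_row, "-")^2 +
        outer(tr_c, rec$centroid_col, "-")^2
      d_um <- sqrt(d_um) * pixel_size_um
      lim <- max_displacement_um * gaps
      cand <- which(d_um <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        dd <- d_um[cand]
        ord <- order(dd, active[cand[, 1]], rec$object_id[cand[, 2]])
        for (k in ord) {
          ti <- cand[k, 1]; di <- cand[k, 2]
          if (assigned_track[ti] || assigned_det[di]) next
          assigned_track[ti] <- TRUE
          assigned_det[di] <- TRUE
          id <- active[ti]
          t <- tracks[[id]]
          t$frames <- c(t$frames, fi)
          t$rows <- c(t$rows, rec$centroid_row[di])
          t$cols <- c(t$cols, rec$centroid_col[di])
          t$object_id <- c(t$object_id, rec$object_id[di])
          t$time <- c(t$time, rec$time_point_min[di])
          t$area <- c(t$area, rec$target_area_ch2_um2[di])
          t$intensity <- c(t$intensity, rec$avg_intensity_ch2[di])
          tracks[[id]] <- t
          last_seen[ti] <- fi
        }
      }
    }
    if (nrow(rec)) {
      for (di in which(!assigned_det)) {
        id <- new_track(rec[di, ], fi)
        active <- c(active, id)
        last_seen <- c(last_seen, fi)
        assigned_track <- c(assigned_track, TRUE)
      }
    }
  }

  frame_times <- times
  if (anyNA(frame_times)) {
    # interpolate times of empty frames from their neighbours' spacing
    frame_times <- stats::approx(known, times[known], xout = seq_len(n_frames),
                                 rule = 2)$y
  }
  lapply(tracks, function(t) {
    span <- seq(min(t$frames), max(t$frames))
    m <- match(span, t$frames)
    entries <- data.frame(
      frame = span,
      time_point_min = frame_times[span],
      object_id = ifelse(is.na(m), NA_integer_, t$object_id[m]),
      centroid_row = ifelse(is.na(m), NA_real_, t$rows[m]),
      centroid_col = ifelse(is.na(m), NA_real_, t$cols[m]),
      target_area_ch2_um2 = ifelse(is.na(m), NA_real_, t$area[m]),
      avg_intensity_ch2 = ifelse(is.na(m), NA_real_, t$intensity[m]),
      stringsAsFactors = FALSE
    )
    structure(list(track_id = t$track_id, entries = entries),
              class = "cell_track")
  })
}

#' Classify a track's death trajectory
#'
#' `LIVE` when the intensity gate never passes; `NETOSIS` when the gate
#' passes and the dye-positive area reaches the area gate at or after
#' first permeability; `NECROSIS` when the gate passes, the area stays
#' below the gate for the rest of the track, and the track persists at
#' least `min_follow_min` after first permeability (otherwise later
#' decondensation could not be ruled out); `AMBIGUOUS` otherwise.
#'
#' @param track a `cell_track` from [link_frames] with >= 3 detected
#'   entries.
#' @param refs a [reference_levels].
#' @param min_follow_min required follow-up after first permeability
#'   before calling necrosis. Default 45 (three 15-min frames).
#' @return list with `fate`, `first_permeable_min` (`NA` when never
#'   permeable) and `max_area_um2`.
#' @export
classify_trajectory <- function(track, refs, min_follow_min = 45) {
  e <- track$entries[!is.na(track$entries$object_id), , drop = FALSE]
  if (nrow(e) < 3L) {
    ns_stop("track too short to classify (need >= 3 detected entries)",
            "netscan_track_error")
  }
  permeable <- e$avg_intensity_ch2 >= refs$intensity_ref
  max_area <- max(e$target_area_ch2_um2)
  if (!any(permeable)) {
    return(list(fate = "LIVE", first_permeable_min = NA_real_,
                max_area_um2 = max_area))
  }
  t0 <- e$time_point_min[which(permeable)[1]]
  after <- e$time_point_min >= t0
  max_area_after <- max(e$target_area_ch2_um2[after])
  fate <- if (max_area_after >= refs$area_ref_um2) {
    "NETOSIS"
  } else if (max(e$time_point_min) - t0 >= min_follow_min) {
    "NECROSIS"
  } else {
    "AMBIGUOUS"
  }
  list(fate = fate, first_permeable_min = t0,
       max_area_um2 = max_area_after)
}

#' Flatten tracks into a long table
#'
#' @param tracks list of `cell_track` objects.
#' @param fates optional character vector of fates aligned with `tracks`.
#' @return data.frame with columns `track_id, t_min, object_id, area,
#'   intensity, fate`.
#' @export
track_table <- function(tracks, fates = NULL) {
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    e <- tracks[[i]]$entries
    data.frame(
      track_id = tracks[[i]]$track_id,
      t_min = e$time_point_min,
      object_id = e$object_id,
      area = e$target_area_ch2_um2,
      intensity = e$avg_intensity_ch2,
      fate = if (is.null(fates)) NA_character_ else fates[i],
      stringsAsFactors = FALSE
    )
  }))
}
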