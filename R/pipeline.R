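# End-to-end orchestration: preprocess -> segment -> target mask ->
# features -> reference levels -> classification -> summaries -> group
# statistics. Reference levels are estimated once per plate (pooled over
# wells) so every treatment shares the same gates, mirroring a single
# scan-setting per plate. Field-level failures are isolated by default:
# a failing field is logged and skipped, the rest of the plate proceeds.

#' Analysis parameter bundle
#'
#' Collects the per-stage parameter objects plus the plate-level knobs in
#' one place; every run's manifest records the effective values.
#'
#' @param preprocess a [preprocess_params].
#' @param segmentation a [segmentation_params].
#' @param target a [target_mask_params].
#' @param ch2_mad_k robust per-field pixel threshold for the
#'   impermeable-DNA channel: median + `ch2_mad_k` x MAD of the
#'   background-corrected pixels. Default 5.
#' @param area_multiplier,min_control_objects,bimodality_cutoff passed to
#'   [estimate_reference_levels].
#' @param annexin_ring_ref,annexin_cv_ref four-channel gates.
#' @return an `analysis_params` list.
#' @export
analysis_params <- function(preprocess = preprocess_params(),
                            segmentation = segmentation_params(),
                            target = target_mask_params(),
                            ch2_mad_k = 5,
                            area_multiplier = 2,
                            min_control_objects = 50L,
                            bimodality_cutoff = 0.555,
                            annexin_ring_ref = 2,
                            annexin_cv_ref = 0.8) {
  structure(
    list(
      preprocess = preprocess,
      segmentation = segmentation,
      target = target,
      ch2_mad_k = ch2_mad_k,
      area_multiplier = area_multiplier,
      min_control_objects = min_control_objects,
      bimodality_cutoff = bimodality_cutoff,
      annexin_ring_ref = annexin_ring_ref,
      annexin_cv_ref = annexin_cv_ref
    ),
    class = "analysis_params"
  )
}

#' Analyze a single field: segmentation through feature measurement
#'
#' @param field a [field_image].
#' @param params an [analysis_params].
#' @param four_channel compute Annexin descriptors.
#' @return list with `records` (data.frame), `nuclei` and `targets`
#'   ([labeled_mask]s) and the per-field `ch2_threshold`.
#' @export
analyze_field <- function(field, params = analysis_params(),
                          four_channel = FALSE) {
  ch1 <- field$channels$NUCLEUS_ALL
  ch2 <- field$channels$IMPERMEABLE_DNA
  if (is.null(ch2)) {
    ns_stop("field lacks an IMPERMEABLE_DNA channel", "netscan_config_error")
  }
  ch1_corr <- correct_background(ch1, params$preprocess)
  ch1_seg <- if (params$preprocess$smooth_for_segmentation) {
    smooth(ch1_corr, params$preprocess)
  } else {
    ch1_corr
  }
  nuclei <- identify_primary_objects(ch1_seg, params$segmentation)
  ch2_corr <- correct_background(ch2, params$preprocess)
  ch2_thr <- robust_pixel_threshold(ch2_corr$pixels, params$ch2_mad_k)
  ch2_fg <- identify_ch2_foreground(ch2_corr, ch2_thr)
  targets <- build_target_mask(nuclei, params$target, field$pixel_size_um)
  meas_channels <- list(NUCLEUS_ALL = ch1_corr, IMPERMEABLE_DNA = ch2_corr)
  if (four_channel) {
    ann <- field$channels$ANNEXIN
    if (is.null(ann)) {
      ns_stop("FOUR_CHANNEL mode requires an ANNEXIN channel",
              "netscan_config_error")
    }
    meas_channels$ANNEXIN <- correct_background(ann, params$preprocess)
  }
  meas_field <- field_image(meas_channels, field$well_id, field$field_index,
                            field$time_point_min)
  records <- measure_objects(meas_field, nuclei, targets, ch2_fg,
                             params$target, four_channel = four_channel)
  list(records = records, nuclei = nuclei, targets = targets,
       ch2_threshold = ch2_thr)
}

# resolve the input fields of a plate run: in-memory list or TIFFs on disk
#' @noRd
resolve_fields <- function(layout, fields = NULL, image_dir = NULL,
                           time_point_min = 0) {
  if (!is.null(fields)) return(fields)
  if (is.null(image_dir)) {
    ns_stop("either in-memory fields or image_dir must be given",
            "netscan_config_error")
  }
  roles <- mode_channels(layout$mode)
  out <- list()
  for (w in layout$wells$well_id) {
    for (f in seq_len(layout$fields_per_well)) {
      paths <- stats::setNames(file.path(
        image_dir, field_file_name(w, f, time_point_min, roles)
      ), roles)
      out[[length(out) + 1L]] <- read_field(
        paths, well_id = w, field_index = f,
        time_point_min = time_point_min,
        pixel_size_um = layout$pixel_size_um
      )
    }
  }
  out
}

#' Analyze a plate end to end
#'
#' Runs every field through [analyze_field], estimates reference levels
#' once over the pooled plate (unless manual `gates` are supplied),
#' classifies every cell, summarizes per well (border objects excluded),
#' and compares treatment groups on `pct_net` when at least two groups
#' have two or more replicate wells.
#'
#' @param layout a [plate_layout].
#' @param fields optional list of in-memory [field_image] objects (their
#'   `well_id`/`field_index` metadata place them on the plate).
#' @param image_dir optional directory of channel TIFFs named per
#'   [field_file_name]; used when `fields` is `NULL`.
#' @param params an [analysis_params].
#' @param gates optional manual [reference_levels]; skips estimation.
#' @param strict when `TRUE` any field failure aborts the run; default
#'   logs and skips the failing field.
#' @param out_dir optional output directory passed to [write_results].
#' @param keep_masks retain segmentation masks in the return value (and
#'   write them when `out_dir` is set).
#' @return list with `records`, `classes`, `summaries`, `refs`,
#'   `comparison` (or `NULL`), `response` (concentration-response table
#'   when concentrations are present), `manifest`, and `failed_fields`.
#' @export
analyze_plate <- function(layout, fields = NULL, image_dir = NULL,
                          params = analysis_params(), gates = NULL,
                          strict = FALSE, out_dir = NULL,
                          keep_masks = FALSE) {
  four <- layout$mode == "FOUR_CHANNEL"
  fields <- resolve_fields(layout, fields, image_dir)
  known_wells <- layout$wells$well_id
  records_list <- list()
  masks <- list()
  failed <- character(0)
  for (fi in seq_along(fields)) {
    fld <- fields[[fi]]
    tag <- sprintf("%s_f%02d", fld$well_id, fld$field_index)
    if (!fld$well_id %in% known_wells) {
      ns_stop(paste("field well not in layout:", fld$well_id),
              "netscan_config_error")
    }
    res <- if (strict) {
      analyze_field(fld, params, four_channel = four)
    } else {
      tryCatch(analyze_field(fld, params, four_channel = four),
               error = function(e) {
                 message(sprintf("[netscan] field %s failed: %s", tag,
                                 conditionMessage(e)))
                 NULL
               })
    }
    if (is.null(res)) {
      failed <- c(failed, tag)
      next
    }
    records_list[[tag]] <- res$records
    if (keep_masks) masks[[tag]] <- res$nuclei
  }
  records <- do.call(rbind, records_list)
  rownames(records) <- NULL
  if (is.null(records) || !nrow(records)) {
    ns_stop("no objects detected on the plate", "netscan_estimation_error")
  }
  refs <- gates %||% estimate_reference_levels(
    records[!records$border, , drop = FALSE], layout,
    area_multiplier = params$area_multiplier,
    min_control_objects = params$min_control_objects,
    bimodality_cutoff = params$bimodality_cutoff,
    annexin_ring_ref = params$annexin_ring_ref,
    annexin_cv_ref = params$annexin_cv_ref
  )
  classes <- if (four) classify_four_channel(records, refs)
  else classify_two_channel(records, refs)
  summaries <- do.call(rbind, lapply(known_wells, function(w) {
    sel <- records$well_id == w & !records$border
    s <- summarize_well(records[sel, , drop = FALSE], classes[sel], w,
                        treatment = layout$wells$treatment[
                          layout$wells$well_id == w])
    s
  }))
  rownames(summaries) <- NULL
  comparison <- NULL
  grp <- split(summaries$pct_net[!summaries$undefined],
               summaries$treatment[!summaries$undefined])
  grp <- grp[vapply(grp, length, integer(1)) >= 2L]
  if (length(grp) >= 2L) comparison <- compare_groups(grp)
  response <- NULL
  if (!anyNA(layout$wells$concentration) &&
      length(unique(layout$wells$concentration)) > 1L) {
    response <- build_response_table(summaries[!summaries$undefined, ,
                                               drop = FALSE],
                                     layout, axis = "CONCENTRATION")
  }
  manifest_extra <- list(
    mode = layout$mode,
    gates = list(
      intensity_ref = refs$intensity_ref,
      area_ref_um2 = refs$area_ref_um2,
      annexin_ring_ref = refs$annexin_ring_ref,
      annexin_cv_ref = refs$annexin_cv_ref,
      provenance = refs$provenance
    ),
    parameters = params_to_list(params),
    n_objects = nrow(records),
    n_fields = length(fields) - length(failed),
    failed_fields = failed
  )
  manifest <- manifest_extra
  if (!is.null(out_dir)) {
    manifest <- write_results(records, summaries,
                              masks = if (keep_masks) masks else list(),
                              out_dir = out_dir,
                              manifest_extra = manifest_extra)
  }
  list(records = records, classes = classes, summaries = summaries,
       refs = refs, comparison = comparison, response = response,
       masks = if (keep_masks) masks else NULL,
       manifest = manifest, failed_fields = failed)
}

#' @noRd
params_to_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), params_to_list) else x
}

#' Analyze a time-lapse series end to end
#'
#' Each frame is analyzed statically, reference levels are estimated from
#' the pooled records (or taken from `gates`), detections are linked into
#' tracks per well, and each sufficiently long track receives a death
#' fate via [classify_trajectory]. Per-frame percent NETosis is reported
#' alongside the per-well fate fractions.
#'
#' @param layout a [plate_layout] with `time_series` set.
#' @param fields list of [field_image] objects covering every
#'   (well, time point), or `NULL` to read from `image_dir`.
#' @param image_dir optional TIFF directory (naming per
#'   [field_file_name]).
#' @param params an [analysis_params].
#' @param gates optional manual [reference_levels].
#' @param max_displacement_um,max_gap,min_follow_min tracking and fate
#'   parameters (see [link_frames], [classify_trajectory]).
#' @return list with `tracks`, `track_fates`, `fate_summary` (per-well
#'   fate fractions), `frame_summaries` (per well and time point),
#'   `refs` and `manifest`.
#' @export
analyze_timelapse <- function(layout, fields = NULL, image_dir = NULL,
                              params = analysis_params(), gates = NULL,
                              max_displacement_um = 10, max_gap = 1L,
                              min_follow_min = 45) {
  times <- layout$time_series
  if (is.null(times) || length(times) < 2L) {
    ns_stop("time-lapse analysis needs a layout time_series with >= 2 points (use analyze_plate for single scans)",
            "netscan_config_error")
  }
  four <- layout$mode == "FOUR_CHANNEL"
  if (is.null(fields)) {
    fields <- list()
    for (t in times) {
      fields <- c(fields, resolve_fields(layout, NULL, image_dir,
                                         time_point_min = t))
    }
  }
  # static analysis of every frame
  per_field <- lapply(fields, function(fld) {
    res <- analyze_field(fld, params, four_channel = four)
    res$records
  })
  records <- do.call(rbind, per_field)
  rownames(records) <- NULL
  refs <- gates %||% estimate_reference_levels(
    records[!records$border, , drop = FALSE], layout,
    area_multiplier = params$area_multiplier,
    min_control_objects = params$min_control_objects,
    bimodality_cutoff = params$bimodality_cutoff
  )
  classes <- if (four) classify_four_channel(records, refs)
  else classify_two_channel(records, refs)

  frame_summaries <- do.call(rbind, lapply(layout$wells$well_id, function(w) {
    do.call(rbind, lapply(times, function(t) {
      sel <- records$well_id == w & records$time_point_min == t &
        !records$border
      s <- summarize_well(records[sel, , drop = FALSE], classes[sel], w)
      s$time_point_min <- t
      s
    }))
  }))
  rownames(frame_summaries) <- NULL

  all_tracks <- list()
  fate_rows <- list()
  for (w in layout$wells$well_id) {
    frames_w <- lapply(times, function(t) {
      records[records$well_id == w & records$time_point_min == t &
                !records$border, , drop = FALSE]
    })
    tracks <- link_frames(frames_w, pixel_size_um = layout$pixel_size_um,
                          max_displacement_um = max_displacement_um,
                          max_gap = max_gap)
    fates <- vapply(tracks, function(tr) {
      n_det <- sum(!is.na(tr$entries$object_id))
      if (n_det < 3L) return("TOO_SHORT")
      classify_trajectory(tr, refs, min_follow_min = min_follow_min)$fate
    }, character(1))
    all_tracks[[w]] <- tracks
    tab <- table(factor(fates, c("LIVE", "NETOSIS", "NECROSIS",
                                 "AMBIGUOUS", "TOO_SHORT")))
    fate_rows[[w]] <- data.frame(
      well_id = w, n_tracks = length(tracks),
      n_live = as.integer(tab["LIVE"]),
      n_netosis = as.integer(tab["NETOSIS"]),
      n_necrosis = as.integer(tab["NECROSIS"]),
      n_ambiguous = as.integer(tab["AMBIGUOUS"]),
      n_too_short = as.integer(tab["TOO_SHORT"]),
      stringsAsFactors = FALSE
    )
  }
  fate_summary <- do.call(rbind, fate_rows)
  rownames(fate_summary) <- NULL
  track_fates <- lapply(all_tracks, function(tracks) {
    vapply(tracks, function(tr) {
      n_det <- sum(!is.na(tr$entries$object_id))
      if (n_det < 3L) return("TOO_SHORT")
      classify_trajectory(tr, refs, min_follow_min = min_follow_min)$fate
    }, character(1))
  })
  list(
    tracks = all_tracks,
    track_fates = track_fates,
    fate_summary = fate_summary,
    frame_summaries = frame_summaries,
    records = records,
    classes = classes,
    refs = refs,
    manifest = list(
      mode = layout$mode,
      gates = list(intensity_ref = refs$intensity_ref,
                   area_ref_um2 = refs$area_ref_um2,
                   provenance = refs$provenance),
      parameters = params_to_list(params),
      tracking = list(max_displacement_um = max_displacement_um,
                      max_gap = max_gap, min_follow_min = min_follow_min)
    )
  )
}
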