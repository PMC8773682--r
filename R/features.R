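# Per-object measurement of the gating features.
#
# Each nucleus gets a "target region": its mask dilated by a fixed radius,
# with contested pixels assigned to the nearer object centroid. Inside that
# region we measure the impermeable-dye (Ch2) foreground area
# (target_area_ch2_um2) and mean Ch2 intensity (avg_intensity_ch2) — the
# two features the NET gate runs on — plus optional Annexin V descriptors
# (boundary-shell ring ratio and coefficient of variation) that separate
# surface-localized from punctate staining in the four-channel mode.

#' Target-mask parameters
#'
#' @param dilation_um radius by which each nuclear mask is dilated to form
#'   its target region. The default 8 um keeps a decondensed NET cloud
#'   (several-fold nuclear expansion) inside its own cell's region.
#' @param shell_width_um width of the boundary shell used for the Annexin
#'   ring ratio. Default 1.5 um.
#' @return a `target_mask_params` list.
#' @export
target_mask_params <- function(dilation_um = 8, shell_width_um = 1.5) {
  if (dilation_um < 0) {
    ns_stop("dilation_um must be >= 0", "netscan_param_error")
  }
  if (shell_width_um <= 0) {
    ns_stop("shell_width_um must be > 0", "netscan_param_error")
  }
  structure(
    list(dilation_um = dilation_um, shell_width_um = shell_width_um),
    class = "target_mask_params"
  )
}

# centroids (row, col) of a label matrix, 1-based pixel centers
#' @noRd
label_centroids <- function(labels, n) {
  idx <- which(labels > 0L)
  l <- labels[idx]
  r <- ((idx - 1L) %% nrow(labels)) + 1L
  c <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tabulate(l, nbins = n)
  cbind(
    row = rowsum(as.numeric(r), l)[, 1] / area,
    col = rowsum(as.numeric(c), l)[, 1] / area
  )
}

# bounding box of label i, expanded by pad and clipped to the image
#' @noRd
label_bbox <- function(labels, i, pad) {
  idx <- which(labels == i)
  r <- ((idx - 1L) %% nrow(labels)) + 1L
  c <- ((idx - 1L) %/% nrow(labels)) + 1L
  list(
    r = max(1L, min(r) - pad):min(nrow(labels), max(r) + pad),
    c = max(1L, min(c) - pad):min(ncol(labels), max(c) + pad)
  )
}

#' Build per-object target regions by constrained dilation
#'
#' Each object's target region is its nuclear mask dilated by
#' `dilation_um` (Euclidean disc). Where the dilations of two objects
#' overlap, each contested pixel is assigned to the object with the nearer
#' centroid (ties to the lower label), so target regions partition their
#' union and measurements stay single-cell even when NET clouds from
#' adjacent cells merge.
#'
#' @param mask nuclei [labeled_mask].
#' @param params a [target_mask_params].
#' @param pixel_size_um physical pixel size.
#' @return a [labeled_mask] of target regions with the same label ids.
#' @export
build_target_mask <- function(mask, params = target_mask_params(),
                              pixel_size_um = 0.65) {
  labs <- mask$labels
  n <- mask$n_objects
  r_px <- um_to_px(params$dilation_um, pixel_size_um)
  if (n == 0L || r_px == 0) {
    return(labeled_mask(labs, border_labels = mask$border_labels))
  }
  pad <- as.integer(ceiling(r_px)) + 1L
  cent <- label_centroids(labs, n)
  targets <- matrix(0L, nrow(labs), ncol(labs))
  bestd <- matrix(Inf, nrow(labs), ncol(labs))
  for (i in seq_len(n)) {
    bb <- label_bbox(labs, i, pad)
    sub <- labs[bb$r, bb$c, drop = FALSE] == i
    # Euclidean distance of every window pixel to object i
    d <- EBImage::distmap(matrix(as.numeric(!sub), nrow(sub), ncol(sub)))
    cover <- d <= r_px
    if (!any(cover)) next
    rr <- matrix(bb$r, length(bb$r), length(bb$c))
    cc <- matrix(bb$c, length(bb$r), length(bb$c), byrow = TRUE)
    cd <- (rr - cent[i, "row"])^2 + (cc - cent[i, "col"])^2
    win_best <- bestd[bb$r, bb$c, drop = FALSE]
    win_lab <- targets[bb$r, bb$c, drop = FALSE]
    take <- cover & (cd < win_best)  # strict: earlier (lower) label wins ties
    win_best[take] <- cd[take]
    win_lab[take] <- i
    bestd[bb$r, bb$c] <- win_best
    targets[bb$r, bb$c] <- win_lab
  }
  labeled_mask(targets, border_labels = mask$border_labels)
}

#' Measure per-object gating features
#'
#' Produces one row per nucleus label, sorted by `object_id`, with the
#' columns gated on downstream: `area_ch1_um2` (nuclear area),
#' `target_area_ch2_um2` (impermeable-dye foreground area inside the
#' target region), `avg_intensity_ch2` (mean Ch2 over the full target
#' region, so the gate is sensitive to both brightness and spatial
#' extent), `avg_intensity_ch1`, and in four-channel mode the Annexin
#' descriptors of [annexin_descriptors]. Intensities are expected to be
#' measured on background-corrected, unsmoothed channels.
#'
#' @param field a [field_image] with background-corrected channels.
#' @param nuclei nuclei [labeled_mask].
#' @param targets target-region [labeled_mask] from [build_target_mask].
#' @param ch2_foreground logical matrix from [identify_ch2_foreground].
#' @param params a [target_mask_params].
#' @param four_channel compute Annexin descriptors (requires an `ANNEXIN`
#'   channel).
#' @return data.frame of cell records.
#' @export
measure_objects <- function(field, nuclei, targets, ch2_foreground,
                            params = target_mask_params(),
                            four_channel = FALSE) {
  labs <- nuclei$labels
  if (!all(dim(labs) == dim(targets$labels)) ||
      !all(dim(labs) == dim(ch2_foreground))) {
    ns_stop("mask dimensions do not match", "netscan_dim_error")
  }
  n <- nuclei$n_objects
  psz <- field$pixel_size_um
  ch1 <- field$channels$NUCLEUS_ALL$pixels
  ch2 <- field$channels$IMPERMEABLE_DNA$pixels
  if (is.null(ch2)) {
    ns_stop("IMPERMEABLE_DNA channel required for measurement",
            "netscan_config_error")
  }
  empty <- data.frame(
    object_id = integer(0), well_id = character(0),
    field_index = integer(0), time_point_min = numeric(0),
    centroid_row = numeric(0), centroid_col = numeric(0),
    area_ch1_um2 = numeric(0), target_area_ch2_um2 = numeric(0),
    avg_intensity_ch2 = numeric(0), avg_intensity_ch1 = numeric(0),
    annexin_ring_ratio = numeric(0), annexin_cv = numeric(0),
    border = logical(0), stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)

  nuc_idx <- which(labs > 0L)
  nuc_lab <- labs[nuc_idx]
  area_ch1_px <- tabulate(nuc_lab, nbins = n)
  cent <- label_centroids(labs, n)
  avg_ch1 <- rowsum(ch1[nuc_idx], nuc_lab)[, 1] / area_ch1_px

  tg <- targets$labels
  tg_idx <- which(tg > 0L)
  tg_lab <- tg[tg_idx]
  tg_area_px <- tabulate(tg_lab, nbins = n)
  sum_ch2 <- rep(0, n)
  if (length(tg_idx)) {
    s <- rowsum(ch2[tg_idx], tg_lab)
    sum_ch2[as.integer(rownames(s))] <- s[, 1]
  }
  avg_ch2 <- ifelse(tg_area_px > 0, sum_ch2 / tg_area_px, 0)

  fg_idx <- which(tg > 0L & ch2_foreground)
  target_area_px <- rep(0, n)
  if (length(fg_idx)) {
    ta <- table(tg[fg_idx])
    target_area_px[as.integer(names(ta))] <- as.numeric(ta)
  }

  rec <- data.frame(
    object_id = seq_len(n),
    well_id = field$well_id,
    field_index = field$field_index,
    time_point_min = field$time_point_min,
    centroid_row = cent[, "row"] - 1,  # 0-based pixel coordinates
    centroid_col = cent[, "col"] - 1,
    area_ch1_um2 = px2_to_um2(area_ch1_px, psz),
    target_area_ch2_um2 = px2_to_um2(target_area_px, psz),
    avg_intensity_ch2 = avg_ch2,
    avg_intensity_ch1 = avg_ch1,
    annexin_ring_ratio = NA_real_,
    annexin_cv = NA_real_,
    border = seq_len(n) %in% nuclei$border_labels,
    stringsAsFactors = FALSE
  )
  if (four_channel) {
    ann <- annexin_descriptors(field, nuclei, targets, params)
    rec$annexin_ring_ratio <- ann$ring_ratio
    rec$annexin_cv <- ann$cv
  }
  rec[order(rec$object_id), , drop = FALSE]
}

#' Annexin V distribution descriptors
#'
#' For each object: `ring_ratio` is the mean Annexin intensity in the
#' perinuclear shell — the band of `shell_width_um` just outside the
#' nuclear mask, clipped to the object's target region — divided by the
#' mean over the nuclear interior plus a 1-intensity-unit stabilizer.
#' In a shrunken apoptotic cell the plasma membrane hugs the condensed
#' nucleus, so surface-localized staining lights up exactly this band
#' while the nucleus stays dark, giving ratios well above 1; the
#' scattered punctate staining of lysed NET-forming cells covers nucleus
#' and surroundings alike and stays near (or below) 1. `cv` is the
#' coefficient of variation of Annexin over the whole target region;
#' punctate staining gives large values.
#'
#' @inheritParams measure_objects
#' @return data.frame with columns `object_id`, `ring_ratio`, `cv`.
#' @export
annexin_descriptors <- function(field, nuclei, targets,
                                params = target_mask_params()) {
  ann_ch <- field$channels$ANNEXIN
  if (is.null(ann_ch)) {
    ns_stop("ANNEXIN channel required for annexin_descriptors",
            "netscan_config_error")
  }
  ann <- ann_ch$pixels
  tg <- targets$labels
  nl <- nuclei$labels
  n <- nuclei$n_objects
  shell_px <- um_to_px(params$shell_width_um, field$pixel_size_um)
  eps <- 1
  ring_ratio <- rep(NA_real_, n)
  cv <- rep(NA_real_, n)
  pad <- as.integer(ceiling(shell_px)) + 1L
  for (i in seq_len(n)) {
    bb <- label_bbox(nl, i, pad)
    nuc <- nl[bb$r, bb$c, drop = FALSE] == i
    reg <- tg[bb$r, bb$c, drop = FALSE] == i
    # distance of every window pixel to the nuclear mask of object i
    d <- EBImage::distmap(matrix(as.numeric(!nuc), nrow(nuc), ncol(nuc)))
    shell <- d > 0 & d <= shell_px & reg
    awin <- ann[bb$r, bb$c]
    mean_nuc <- mean(awin[nuc])
    mean_shell <- if (any(shell)) mean(awin[shell]) else 0
    ring_ratio[i] <- mean_shell / (mean_nuc + eps)
    vals <- ann[which(tg == i)]
    m <- if (length(vals)) mean(vals) else 0
    cv[i] <- if (length(vals) > 1L) stats::sd(vals) / (m + eps) else 0
  }
  data.frame(object_id = seq_len(n), ring_ratio = ring_ratio, cv = cv)
}
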