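# Primary object identification on the Hoechst channel.
#
# The automatic threshold is Otsu's bimodal split scaled by a factor < 1
# (default 0.6) so that even the dimmest nuclei — dye-spent NET remnants
# and condensed apoptotic nuclei — are still captured. Touching nuclei are
# split by a watershed on the negated Euclidean distance transform with
# seed suppression scaled by the expected nuclear radius.

#' Segmentation parameters
#'
#' @param threshold_method `"OTSU_SCALED"` (automatic bimodal threshold
#'   times `threshold_scale`) or `"FIXED"`.
#' @param threshold_scale multiplier in (0, 2] applied to the automatic
#'   threshold; the default 0.6 keeps dim objects.
#' @param fixed_threshold intensity used when `threshold_method = "FIXED"`.
#' @param segmentation_radius_um expected nuclear radius (um) used to
#'   suppress spurious watershed seeds when splitting touching nuclei.
#' @param min_object_area_um2 objects smaller than this are discarded.
#' @param exclude_border flag border-touching objects so quantification
#'   can drop them (they are kept in the mask and object table).
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_method = c("OTSU_SCALED", "FIXED"),
                                threshold_scale = 0.6,
                                fixed_threshold = NULL,
                                segmentation_radius_um = 4,
                                min_object_area_um2 = 12,
                                exclude_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_scale <= 0 || threshold_scale > 2) {
    ns_stop("threshold_scale must be in (0, 2]", "netscan_param_error")
  }
  if (segmentation_radius_um <= 0) {
    ns_stop("segmentation_radius_um must be > 0", "netscan_param_error")
  }
  if (min_object_area_um2 <= 0) {
    ns_stop("min_object_area_um2 must be > 0", "netscan_param_error")
  }
  if (threshold_method == "FIXED" && is.null(fixed_threshold)) {
    ns_stop("FIXED threshold_method requires fixed_threshold",
            "netscan_param_error")
  }
  structure(
    list(
      threshold_method = threshold_method,
      threshold_scale = threshold_scale,
      fixed_threshold = fixed_threshold,
      segmentation_radius_um = segmentation_radius_um,
      min_object_area_um2 = min_object_area_um2,
      exclude_border = exclude_border
    ),
    class = "segmentation_params"
  )
}

#' Compute the foreground threshold for a channel
#'
#' @param img a [channel_image] (preprocessed).
#' @param params a [segmentation_params].
#' @return scalar intensity threshold.
#' @export
compute_threshold <- function(img, params = segmentation_params()) {
  if (params$threshold_method == "FIXED") {
    if (is.null(params$fixed_threshold)) {
      ns_stop("FIXED threshold_method requires fixed_threshold",
              "netscan_param_error")
    }
    return(params$fixed_threshold)
  }
  px <- img$pixels
  if (max(px) - min(px) < .Machine$double.eps) {
    ns_stop("constant image: no foreground/background separation",
            "netscan_degenerate_error")
  }
  maxv <- 2^img$bit_depth - 1
  thr <- EBImage::otsu(EBImage::Image(px / maxv), range = c(0, 1),
                       levels = 256L) * maxv
  thr * params$threshold_scale
}

# labels touching any image edge
#' @noRd
border_labels_of <- function(labels) {
  edge <- c(labels[1, ], labels[nrow(labels), ],
            labels[, 1], labels[, ncol(labels)])
  sort(unique(edge[edge > 0L]))
}

#' Identify primary objects (nuclei) on the Hoechst channel
#'
#' Thresholds the preprocessed nucleus channel, splits touching nuclei by
#' a distance-transform watershed (seed suppression radius
#' `segmentation_radius_um`, h-maxima tolerance 0.5 px), removes objects
#' below `min_object_area_um2` and relabels densely. Border-touching
#' objects are flagged in `border_labels` (and retained in the mask).
#'
#' @param img preprocessed `NUCLEUS_ALL` [channel_image].
#' @param params a [segmentation_params].
#' @return a [labeled_mask].
#' @export
identify_primary_objects <- function(img, params = segmentation_params()) {
  thr <- compute_threshold(img, params)
  fg <- img$pixels >= thr
  if (!any(fg)) {
    return(labeled_mask(matrix(0L, nrow(img$pixels), ncol(img$pixels))))
  }
  r_px <- max(1L, as.integer(round(
    um_to_px(params$segmentation_radius_um, img$pixel_size_um)
  )))
  dm <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  ws <- EBImage::watershed(dm, tolerance = 0.5, ext = r_px)
  labs <- matrix(as.integer(ws), nrow(fg), ncol(fg))
  # size filter in pixel units
  min_px <- um2_to_px2(params$min_object_area_um2, img$pixel_size_um)
  areas <- tabulate(labs[labs > 0L])
  drop <- which(areas < min_px)
  if (length(drop)) labs[labs %in% drop] <- 0L
  labs <- relabel_dense(labs)
  border <- if (params$exclude_border) border_labels_of(labs) else integer(0)
  labeled_mask(labs, border_labels = border)
}

#' Binary foreground mask of the impermeable-DNA channel
#'
#' No size filtering is applied: NET clouds may be diffuse and must not be
#' eroded by object-level filters.
#'
#' @param img `IMPERMEABLE_DNA` [channel_image] (background-corrected).
#' @param threshold intensity threshold (>= 0).
#' @return logical matrix, `TRUE` where `pixels >= threshold`.
#' @export
identify_ch2_foreground <- function(img, threshold) {
  if (threshold < 0) {
    ns_stop("threshold must be >= 0", "netscan_param_error")
  }
  img$pixels >= threshold
}

# robust per-field pixel threshold for the impermeable-DNA channel:
# median + k * MAD of the background-corrected pixels. With mostly
# background pixels this sits just above the noise floor regardless of
# how many (or few) dye-positive cells the field contains.
#' @noRd
robust_pixel_threshold <- function(pixels, k = 5) {
  med <- stats::median(pixels)
  med + k * stats::mad(pixels) + 1e-9
}
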