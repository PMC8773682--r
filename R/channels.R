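#' Channel roles recognized by the pipeline
#'
#' Analysis is anchored on the membrane-permeable DNA stain (Hoechst 33342,
#' `NUCLEUS_ALL`). Membrane-impermeable DNA dyes (Sytox Green, propidium
#' iodide) map to `IMPERMEABLE_DNA`; Annexin V to `ANNEXIN`. Any other
#' channel (e.g. brightfield) is carried as `OTHER` and ignored downstream.
#'
#' @export
CHANNEL_ROLES <- c("NUCLEUS_ALL", "IMPERMEABLE_DNA", "ANNEXIN", "OTHER")

#' Construct a single-channel image
#'
#' @param pixels numeric matrix of non-negative intensities (rows = image
#'   rows, 0-based pixel coordinates are used in all reported centroids).
#' @param bit_depth integer, one of 8, 12, 16.
#' @param channel_role one of [CHANNEL_ROLES].
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @return a `channel_image` object.
#' @export
channel_image <- function(pixels, bit_depth = 16L,
                          channel_role = "OTHER", pixel_size_um = 0.65) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    ns_stop("pixels must be a numeric matrix", "netscan_type_error")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    ns_stop("pixels must have both dimensions >= 1", "netscan_type_error")
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    ns_stop("bit_depth must be 8, 12 or 16", "netscan_type_error")
  }
  maxv <- 2^bit_depth - 1
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > maxv) {
    ns_stop(
      sprintf("pixel values must lie in [0, %d]", maxv),
      "netscan_type_error"
    )
  }
  channel_role <- match.arg(channel_role, CHANNEL_ROLES)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    ns_stop("pixel_size_um must be positive", "netscan_type_error")
  }
  structure(
    list(
      pixels = pixels,
      bit_depth = as.integer(bit_depth),
      channel_role = channel_role,
      pixel_size_um = pixel_size_um
    ),
    class = "channel_image"
  )
}

#' Construct a multi-channel field image
#'
#' A field is one acquired position inside a well: one registered image per
#' channel plus acquisition metadata. A `NUCLEUS_ALL` channel is mandatory
#' because every downstream step is anchored on the Hoechst nuclei.
#'
#' @param channels named list of [channel_image] objects; names are channel
#'   roles and must be unique.
#' @param well_id plate coordinate such as `"B07"`.
#' @param field_index integer >= 1.
#' @param time_point_min acquisition time in minutes (>= 0).
#' @return a `field_image` object.
#' @export
field_image <- function(channels, well_id, field_index = 1L,
                        time_point_min = 0) {
  if (is.null(names(channels)) || anyDuplicated(names(channels))) {
    ns_stop("channels must be a uniquely named list", "netscan_config_error")
  }
  if (!all(names(channels) %in% CHANNEL_ROLES)) {
    ns_stop("channel names must be channel roles", "netscan_config_error")
  }
  if (!"NUCLEUS_ALL" %in% names(channels)) {
    ns_stop("a NUCLEUS_ALL (Hoechst) channel is required",
            "netscan_config_error")
  }
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ns_stop("all channels must share identical dimensions",
            "netscan_dim_error")
  }
  px <- vapply(channels, function(ch) ch$pixel_size_um, numeric(1))
  if (any(abs(px - px[1]) > 1e-12)) {
    ns_stop("all channels must share pixel_size_um", "netscan_dim_error")
  }
  if (field_index < 1) {
    ns_stop("field_index must be >= 1", "netscan_config_error")
  }
  if (time_point_min < 0) {
    ns_stop("time_point_min must be >= 0", "netscan_config_error")
  }
  structure(
    list(
      well_id = as.character(well_id),
      field_index = as.integer(field_index),
      time_point_min = as.numeric(time_point_min),
      channels = channels,
      pixel_size_um = px[1]
    ),
    class = "field_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> %s %dx%d px, %d-bit, %.3g um/px\n",
    x$channel_role, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
    x$pixel_size_um
  ))
  invisible(x)
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf(
    "<field_image> well %s field %d t=%g min, channels: %s\n",
    x$well_id, x$field_index, x$time_point_min,
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Construct a labeled object mask
#'
#' @param labels integer matrix; 0 is background, objects are labeled
#'   `1..n` densely.
#' @param border_labels integer vector of labels touching the image edge.
#' @return a `labeled_mask` object with `n_objects` set.
#' @export
labeled_mask <- function(labels, border_labels = integer(0)) {
  storage.mode(labels) <- "integer"
  u <- sort(unique(labels[labels > 0L]))
  n <- length(u)
  if (n > 0L && !identical(u, seq_len(n))) {
    ns_stop("labels must be dense 1..n", "netscan_type_error")
  }
  structure(
    list(
      labels = labels,
      n_objects = n,
      border_labels = as.integer(border_labels)
    ),
    class = "labeled_mask"
  )
}

# relabel an arbitrary non-negative integer matrix densely, preserving order
#' @noRd
relabel_dense <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L) {
    return(matrix(0L, nrow(labels), ncol(labels)))
  }
  lut <- integer(max(u) + 1L)
  lut[u + 1L] <- seq_along(u)
  out <- matrix(lut[as.integer(labels) + 1L], nrow(labels), ncol(labels))
  storage.mode(out) <- "integer"
  out
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf(
    "<labeled_mask> %dx%d px, %d objects (%d at border)\n",
    nrow(x$labels), ncol(x$labels), x$n_objects, length(x$border_labels)
  ))
  invisible(x)
}
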