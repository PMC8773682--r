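# TIFF and results I/O.
#
# Images are stored one single-plane grayscale TIFF per channel per field.
# Reading goes through the tiff package with as.is = TRUE so stored integer
# values come back unscaled; label masks round-trip bit-exactly as 16-bit.

#' Read one field from per-channel TIFF files
#'
#' @param paths named character vector or list mapping channel roles (see
#'   [CHANNEL_ROLES]) to TIFF file paths.
#' @param well_id,field_index,time_point_min acquisition metadata.
#' @param pixel_size_um physical pixel size shared by all channels.
#' @return a [field_image].
#' @export
read_field <- function(paths, well_id, field_index = 1L,
                       time_point_min = 0, pixel_size_um = 0.65) {
  paths <- as.list(paths)
  if (!"NUCLEUS_ALL" %in% names(paths)) {
    ns_stop("read_field: a NUCLEUS_ALL channel path is required",
            "netscan_config_error")
  }
  channels <- lapply(names(paths), function(role) {
    p <- paths[[role]]
    if (!file.exists(p)) {
      ns_stop(paste("image file not found:", p), "netscan_io_error")
    }
    info <- tiff::readTIFF(p, payload = FALSE)
    if (is.list(info) && !is.null(info$bits.per.sample)) {
      bits <- as.integer(info$bits.per.sample)
    } else {
      bits <- 16L
    }
    if (!bits %in% c(8L, 12L, 16L)) bits <- 16L
    px <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(px)) == 3L) {
      if (dim(px)[3] != 1L) {
        ns_stop(paste("not a single-plane grayscale TIFF:", p),
                "netscan_io_error")
      }
      px <- px[, , 1]
    }
    storage.mode(px) <- "double"
    channel_image(px, bit_depth = bits, channel_role = role,
                  pixel_size_um = pixel_size_um)
  })
  names(channels) <- names(paths)
  field_image(channels, well_id = well_id, field_index = field_index,
              time_point_min = time_point_min)
}

#' Write one field's channels as TIFF files
#'
#' Inverse of [read_field]; file names follow [field_file_name].
#'
#' @param field a [field_image].
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths named by channel role.
#' @export
write_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vapply(names(field$channels), function(role) {
    ch <- field$channels[[role]]
    f <- file.path(dir, field_file_name(field$well_id, field$field_index,
                                        field$time_point_min, role))
    maxv <- 2^ch$bit_depth - 1
    # tiff stores 8 or 16 bits; 12-bit data is carried in a 16-bit container
    store_bits <- if (ch$bit_depth == 8L) 8L else 16L
    store_max <- 2^store_bits - 1
    tiff::writeTIFF(round(ch$pixels) / store_max, f,
                    bits.per.sample = store_bits)
    f
  }, character(1))
  invisible(out)
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask a [labeled_mask] (at most 65535 objects).
#' @param path output file path.
#' @export
write_mask <- function(mask, path) {
  if (mask$n_objects > 65535L) {
    ns_stop("label mask exceeds 16-bit range", "netscan_io_error")
  }
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_mask]
#'
#' @param path TIFF file path.
#' @return a [labeled_mask].
#' @export
read_mask <- function(path) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(px) <- "integer"
  u <- sort(unique(px[px > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    px <- relabel_dense(px)
  }
  labeled_mask(px)
}

#' Write analysis results to disk
#'
#' Writes the per-object table and per-well summary table as
#' comma-separated text with headers, label masks as 16-bit TIFFs, and a
#' JSON manifest listing every file with its row or object count.
#'
#' @param records per-object data.frame (possibly 0 rows) as produced by
#'   [measure_objects].
#' @param summaries per-well summary data.frame as produced by
#'   [summarize_well] rows bound together (possibly 0 rows).
#' @param masks named list of [labeled_mask] objects; names identify the
#'   field (used as file stem).
#' @param out_dir output directory, created if needed.
#' @param manifest_extra optional named list merged into the manifest
#'   (e.g. effective gates and parameters).
#' @return the manifest, invisibly; written as `manifest.json`.
#' @export
write_results <- function(records, summaries, masks = list(), out_dir,
                          manifest_extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    ns_stop(paste("output directory not writable:", out_dir),
            "netscan_io_error")
  }
  obj_path <- file.path(out_dir, "objects.csv")
  sum_path <- file.path(out_dir, "well_summary.csv")
  utils::write.csv(records, obj_path, row.names = FALSE)
  utils::write.csv(summaries, sum_path, row.names = FALSE)
  mask_files <- list()
  if (length(masks)) {
    mask_dir <- file.path(out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    mask_files <- lapply(names(masks), function(nm) {
      p <- file.path(mask_dir, paste0(nm, "_mask.tif"))
      write_mask(masks[[nm]], p)
      list(file = file.path("masks", paste0(nm, "_mask.tif")),
           n_objects = masks[[nm]]$n_objects)
    })
  }
  manifest <- c(
    list(
      software = "netscan",
      version = as.character(utils::packageVersion("netscan")),
      files = list(
        objects = list(file = "objects.csv", n_rows = nrow(records)),
        well_summary = list(file = "well_summary.csv",
                            n_rows = nrow(summaries)),
        masks = mask_files
      )
    ),
    manifest_extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
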