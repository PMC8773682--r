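#' Construct a plate layout
#'
#' The layout maps wells to treatments and analysis roles, fixes the
#' acquisition geometry (fields per well, pixel size) and declares the
#' analysis mode. `TWO_CHANNEL` uses Hoechst + an impermeable DNA dye;
#' `FOUR_CHANNEL` adds Annexin V (and typically swaps Sytox for PI).
#'
#' @param wells data.frame with columns `well_id`, `treatment`,
#'   `concentration` (numeric), `units` (character), `role` (one of
#'   `CONTROL`, `STIMULATED`, `STIMULATED_PLUS_INHIBITOR`, `OTHER`).
#' @param fields_per_well integer >= 1.
#' @param mode `"TWO_CHANNEL"` or `"FOUR_CHANNEL"`.
#' @param pixel_size_um physical pixel size; default 0.65 um/px for a 20x
#'   objective.
#' @param time_series optional numeric vector of acquisition times in
#'   minutes, strictly increasing, for time-lapse plates.
#' @return a `plate_layout` object.
#' @export
plate_layout <- function(wells, fields_per_well = 1L,
                         mode = c("TWO_CHANNEL", "FOUR_CHANNEL"),
                         pixel_size_um = 0.65, time_series = NULL) {
  mode <- match.arg(mode)
  req <- c("well_id", "treatment", "concentration", "units", "role")
  missing_cols <- setdiff(req, names(wells))
  if (length(missing_cols)) {
    ns_stop(
      paste("layout wells missing columns:",
            paste(missing_cols, collapse = ", ")),
      "netscan_config_error"
    )
  }
  wells$well_id <- as.character(wells$well_id)
  if (anyDuplicated(wells$well_id)) {
    dup <- unique(wells$well_id[duplicated(wells$well_id)])
    ns_stop(paste("duplicate well_id:", paste(dup, collapse = ", ")),
            "netscan_config_error")
  }
  valid_roles <- c("CONTROL", "STIMULATED", "STIMULATED_PLUS_INHIBITOR",
                   "OTHER")
  if (!all(wells$role %in% valid_roles)) {
    ns_stop("well roles must be CONTROL / STIMULATED / STIMULATED_PLUS_INHIBITOR / OTHER",
            "netscan_config_error")
  }
  if (fields_per_well < 1) {
    ns_stop("fields_per_well must be >= 1", "netscan_config_error")
  }
  if (!is.null(time_series)) {
    time_series <- as.numeric(time_series)
    if (length(time_series) && any(diff(time_series) <= 0)) {
      ns_stop("time_series must be strictly increasing",
              "netscan_config_error")
    }
  }
  structure(
    list(
      wells = wells,
      fields_per_well = as.integer(fields_per_well),
      mode = mode,
      pixel_size_um = pixel_size_um,
      time_series = time_series
    ),
    class = "plate_layout"
  )
}

#' Load a plate layout from a YAML configuration file
#'
#' Expected top-level keys: `mode`, `pixel_size_um`, `fields_per_well`,
#' optional `time_series`, and `wells` (a list of maps with `well_id`,
#' `treatment`, `concentration`, `units`, `role`).
#'
#' @param config_path path to the YAML file.
#' @param image_dir optional directory; when given, every expected channel
#'   TIFF is checked for existence and missing files raise a configuration
#'   error listing them.
#' @return a `plate_layout` object.
#' @export
load_plate_layout <- function(config_path, image_dir = NULL) {
  if (!file.exists(config_path)) {
    ns_stop(paste("layout config not found:", config_path),
            "netscan_config_error")
  }
  cfg <- yaml::read_yaml(config_path)
  wells <- do.call(rbind, lapply(cfg$wells, function(w) {
    data.frame(
      well_id = as.character(w$well_id),
      treatment = as.character(w$treatment %||% ""),
      concentration = as.numeric(w$concentration %||% NA_real_),
      units = as.character(w$units %||% ""),
      role = as.character(w$role %||% "OTHER"),
      stringsAsFactors = FALSE
    )
  }))
  layout <- plate_layout(
    wells = wells,
    fields_per_well = cfg$fields_per_well %||% 1L,
    mode = cfg$mode %||% "TWO_CHANNEL",
    pixel_size_um = cfg$pixel_size_um %||% 0.65,
    time_series = cfg$time_series
  )
  if (!is.null(image_dir)) {
    files <- plate_file_table(layout)
    missing <- files$file[!file.exists(file.path(image_dir, files$file))]
    if (length(missing)) {
      ns_stop(
        paste0("missing image files (", length(missing), "): ",
               paste(utils::head(missing, 10), collapse = ", ")),
        "netscan_config_error"
      )
    }
  }
  layout
}

# channel roles expected as files for a given mode
#' @noRd
mode_channels <- function(mode) {
  if (mode == "FOUR_CHANNEL") {
    c("NUCLEUS_ALL", "IMPERMEABLE_DNA", "ANNEXIN")
  } else {
    c("NUCLEUS_ALL", "IMPERMEABLE_DNA")
  }
}

#' File name for one channel of one field
#'
#' Flat naming convention: `{well}_f{field:02d}_t{minutes:04d}_{role}.tif`.
#'
#' @param well_id,field_index,time_point_min,channel_role identifying
#'   metadata.
#' @return file name (no directory).
#' @export
field_file_name <- function(well_id, field_index, time_point_min,
                            channel_role) {
  sprintf("%s_f%02d_t%04d_%s.tif", well_id, as.integer(field_index),
          as.integer(round(time_point_min)), channel_role)
}

# full expected file table for a layout
#' @noRd
plate_file_table <- function(layout) {
  times <- layout$time_series %||% 0
  grid <- expand.grid(
    channel_role = mode_channels(layout$mode),
    field_index = seq_len(layout$fields_per_well),
    time_point_min = times,
    well_id = layout$wells$well_id,
    stringsAsFactors = FALSE
  )
  grid$file <- field_file_name(grid$well_id, grid$field_index,
                               grid$time_point_min, grid$channel_role)
  grid
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf(
    "<plate_layout> %d wells, %d fields/well, %s, %.3g um/px%s\n",
    nrow(x$wells), x$fields_per_well, x$mode, x$pixel_size_um,
    if (is.null(x$time_series)) "" else
      sprintf(", %d time points", length(x$time_series))
  ))
  invisible(x)
}
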