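# Event classification.
#
# Two-channel event definitions (the core of the assay):
#   Type 1, NET:          Ch2 intensity gate AND Ch2 area gate
#   Type 2, other death:  Ch2 intensity gate AND NOT area gate
#   Type 3, live:         NOT Ch2 intensity gate
# "Big decondensed nucleus" is operationalized on the Ch2 target area (the
# dye-accessible decondensed DNA cloud), not the Hoechst area, because NET
# DNA stains with the impermeable dye while Hoechst dims. All gates use >=
# (a cell exactly at a reference level is a responder).
#
# Four-channel mode adds Annexin V: surface-localized (high ring ratio)
# small cells are apoptotic (PI may be positive — late apoptosis — or
# negative — early); PI-positive small cells without surface Annexin are
# necrotic. Precedence NET > apoptotic > necrotic, because Annexin V also
# binds NET remnants (decondensation must dominate Annexin positivity) and
# surface Annexin must dominate bare PI positivity to capture late
# apoptosis.

TWO_CHANNEL_CLASSES <- c("TYPE1_NET", "TYPE2_OTHER_DEATH", "TYPE3_LIVE")
FOUR_CHANNEL_CLASSES <- c("NET", "NECROTIC", "APOPTOTIC", "LIVE")

#' Reference levels (gates) for event classification
#'
#' @param intensity_ref Ch2 average-intensity gate: the minimum mean
#'   target-region intensity that counts as dye-positive.
#' @param area_ref_um2 Ch2 target-area gate separating "big decondensed"
#'   from small.
#' @param annexin_ring_ref ring-ratio gate for surface-localized Annexin V
#'   staining (four-channel mode). Default 2.
#' @param annexin_cv_ref CV gate for punctate Annexin V staining; reported
#'   but not required by the default NET branch. Default 0.8.
#' @param provenance `"AUTO"` (estimated) or `"MANUAL"`.
#' @return a `reference_levels` list.
#' @export
reference_levels <- function(intensity_ref, area_ref_um2,
                             annexin_ring_ref = 2, annexin_cv_ref = 0.8,
                             provenance = c("MANUAL", "AUTO")) {
  provenance <- match.arg(provenance)
  if (!is.finite(intensity_ref) || intensity_ref <= 0) {
    ns_stop("intensity_ref must be finite and > 0", "netscan_param_error")
  }
  if (!is.finite(area_ref_um2) || area_ref_um2 <= 0) {
    ns_stop("area_ref_um2 must be finite and > 0", "netscan_param_error")
  }
  structure(
    list(
      intensity_ref = intensity_ref,
      area_ref_um2 = area_ref_um2,
      annexin_ring_ref = annexin_ring_ref,
      annexin_cv_ref = annexin_cv_ref,
      provenance = provenance
    ),
    class = "reference_levels"
  )
}

# 1-D between-class-variance maximization (Otsu on raw values): scan all
# splits of the sorted sample; threshold is the midpoint of the optimal
# split pair.
#' @noRd
otsu_split_1d <- function(x) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x)
  k <- seq_len(n - 1L)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  bcv <- k * (n - k) * (m1 - m2)^2  # global scale factor dropped
  best <- which.max(bcv)
  (x[best] + x[best + 1L]) / 2
}

# Sarle's bimodality coefficient (sample version); uniform ~ 0.555
#' @noRd
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4L) return(0)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  g1 <- (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
  g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  m4 <- sum((x - m)^4) / n
  m2 <- sum((x - m)^2) / n
  g2 <- ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' @export
print.reference_levels <- function(x, ...) {
  cat(sprintf("gates: I* = %.1f (intensity), A* = %.1f um^2 (area), estimated %s\n",
              x$intensity_ref, x$area_ref_um2, x$provenance))
  invisible(x)
}

#' Estimate reference levels from a plate's cell records
#'
#' The intensity gate is the between-class-variance split (1-D Otsu) of
#' `avg_intensity_ch2` pooled over all wells; when the pooled distribution
#' shows no convincing bimodality (Sarle's bimodality coefficient below
#' `bimodality_cutoff`, e.g. an unstimulated plate) the gate falls back to
#' median + 5 x MAD of the control-well intensities. The area gate is
#' `area_multiplier` times the median nuclear area of control-well
#' dye-negative cells.
#'
#' @param records pooled per-object data.frame (border objects included or
#'   not; gating is unaffected).
#' @param layout a [plate_layout]; its `CONTROL` wells anchor the
#'   estimate.
#' @param area_multiplier multiplier on the control median nuclear area;
#'   default 2 ("big decondensed" = at least twice the resting nucleus).
#' @param min_control_objects floor on the number of control-well objects
#'   (default 50) below which estimation refuses and manual gates are
#'   required.
#' @param bimodality_cutoff Sarle's-coefficient cutoff for trusting the
#'   pooled bimodal split. Default 0.555 (the uniform-distribution
#'   benchmark).
#' @param annexin_ring_ref,annexin_cv_ref passed through to
#'   [reference_levels].
#' @return a [reference_levels] with `provenance = "AUTO"`.
#' @export
estimate_reference_levels <- function(records, layout,
                                      area_multiplier = 2,
                                      min_control_objects = 50L,
                                      bimodality_cutoff = 0.555,
                                      annexin_ring_ref = 2,
                                      annexin_cv_ref = 0.8) {
  control_wells <- layout$wells$well_id[layout$wells$role == "CONTROL"]
  if (!length(control_wells)) {
    ns_stop("automatic gate estimation requires at least one CONTROL well",
            "netscan_estimation_error")
  }
  ctrl <- records[records$well_id %in% control_wells, , drop = FALSE]
  if (nrow(ctrl) < min_control_objects) {
    ns_stop(
      sprintf(
        "only %d control-well objects (< %d); set MANUAL reference levels",
        nrow(ctrl), min_control_objects
      ),
      "netscan_estimation_error"
    )
  }
  pooled <- records$avg_intensity_ch2
  bc <- bimodality_coefficient(pooled)
  if (bc >= bimodality_cutoff) {
    intensity_ref <- otsu_split_1d(pooled)
  } else {
    intensity_ref <- stats::median(ctrl$avg_intensity_ch2) +
      5 * stats::mad(ctrl$avg_intensity_ch2)
  }
  intensity_ref <- max(intensity_ref, .Machine$double.eps)
  ch2_neg <- ctrl[ctrl$avg_intensity_ch2 < intensity_ref, , drop = FALSE]
  if (!nrow(ch2_neg)) ch2_neg <- ctrl
  area_ref <- area_multiplier * stats::median(ch2_neg$area_ch1_um2)
  refs <- reference_levels(
    intensity_ref = intensity_ref,
    area_ref_um2 = area_ref,
    annexin_ring_ref = annexin_ring_ref,
    annexin_cv_ref = annexin_cv_ref,
    provenance = "AUTO"
  )
  attr(refs, "bimodality_coefficient") <- bc
  refs
}

#' Two-channel classification: NET / other death / live
#'
#' Implements the three event definitions: `TYPE1_NET` when the Ch2
#' intensity gate and area gate both pass; `TYPE2_OTHER_DEATH` when only
#' the intensity gate passes; `TYPE3_LIVE` when the intensity gate fails
#' (area is ignored for live cells). Gates use `>=`.
#'
#' @param records per-object data.frame (one or more rows) with columns
#'   `avg_intensity_ch2` and `target_area_ch2_um2`.
#' @param refs a [reference_levels].
#' @return character vector of classes, one per row.
#' @export
classify_two_channel <- function(records, refs) {
  dye_pos <- records$avg_intensity_ch2 >= refs$intensity_ref
  big <- records$target_area_ch2_um2 >= refs$area_ref_um2
  ifelse(!dye_pos, "TYPE3_LIVE",
         ifelse(big, "TYPE1_NET", "TYPE2_OTHER_DEATH"))
}

#' Four-channel classification: NET / necrotic / apoptotic / live
#'
#' Fixed evaluation order: (1) NET when the PI gate and the area gate both
#' pass; (2) apoptotic when the Annexin ring-ratio gate passes and the
#' area gate fails (PI may pass — late apoptosis — or fail — early);
#' (3) necrotic when the PI gate passes, the area gate fails and the cell
#' is not apoptotic; (4) live otherwise.
#'
#' @param records per-object data.frame with `avg_intensity_ch2`,
#'   `target_area_ch2_um2` and `annexin_ring_ratio` columns.
#' @param refs a [reference_levels].
#' @return character vector of classes, one per row.
#' @export
classify_four_channel <- function(records, refs) {
  if (anyNA(records$annexin_ring_ratio)) {
    ns_stop("Annexin features missing: four-channel mode requires an ANNEXIN channel",
            "netscan_config_error")
  }
  pi_pos <- records$avg_intensity_ch2 >= refs$intensity_ref
  big <- records$target_area_ch2_um2 >= refs$area_ref_um2
  surface_ann <- records$annexin_ring_ratio >= refs$annexin_ring_ref
  ifelse(pi_pos & big, "NET",
         ifelse(surface_ann & !big, "APOPTOTIC",
                ifelse(pi_pos & !big, "NECROTIC", "LIVE")))
}
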