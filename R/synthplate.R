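# Synthetic ground-truth plate generator.
#
# Renders the four phenotypes the classifier must separate:
#   LIVE       multilobed Hoechst-bright nucleus, no impermeable-dye signal
#   NET        enlarged diffuse dye-bright chromatin cloud (area factor
#              sampled per cell from 2.5-6x the resting nuclear area),
#              dimmed Hoechst over the same decondensed footprint
#   NECROTIC   condensed nucleus, dye-bright, area at or below resting
#   APOPTOTIC  condensed Hoechst-bright nucleus with a surface Annexin V
#              ring; impermeable dye positive only in the late sub-state
# Rendering: ideal per-cell intensity sprites -> Gaussian PSF blur ->
# constant + linear-gradient background -> signal-dependent shot noise +
# Gaussian read noise, all on a 16-bit scale. Every output is a pure
# function of (parameters, seed).

#' Phenotype and rendering model for the synthetic generator
#'
#' Defaults emulate a 96-well neutrophil NETosis assay imaged at 20x
#' (0.65 um/px): resting nuclear radius 3.5 um, NET decondensation factor
#' uniform in 2.5-6x (entirely above the default area-gate multiplier of
#' 2 so ground-truth NETs are separable in expectation), PSF sigma
#' 0.8 um, moderate shot + read noise over a shaded background.
#'
#' @param field_px field edge length in pixels (square fields).
#' @param pixel_size_um physical pixel size.
#' @param bit_depth image bit depth.
#' @param nuclear_radius_um resting (live) nuclear radius.
#' @param net_area_factor_range uniform sampling range of the NET
#'   decondensation area factor.
#' @param min_spacing_um minimum distance between cell centers.
#' @param psf_sigma_um Gaussian point-spread sigma.
#' @param background_level,background_gradient constant background and
#'   left-to-right linear shading amplitude (intensity units).
#' @param read_noise_sd additive Gaussian read noise SD.
#' @param shot_noise_scale multiplier on the sqrt(signal) shot-noise term.
#' @param intensity named list of rendering intensities (see defaults).
#' @param apoptotic_late_frac fraction of apoptotic cells in the late
#'   (dye-permeable) sub-state.
#' @param annexin_ring_width_um width of the rendered surface Annexin
#'   ring.
#' @param live_lobe_radius_frac,live_lobe_offset_frac multilobed live
#'   nucleus geometry: each lobe's radius and center offset as fractions
#'   of `nuclear_radius_um`.
#' @return a `phenotype_model` list.
#' @export
phenotype_model <- function(field_px = 1024L,
                            pixel_size_um = 0.65,
                            bit_depth = 16L,
                            nuclear_radius_um = 3.5,
                            net_area_factor_range = c(2.5, 6),
                            min_spacing_um = 16,
                            psf_sigma_um = 0.8,
                            background_level = 300,
                            background_gradient = 100,
                            read_noise_sd = 40,
                            shot_noise_scale = 1,
                            intensity = list(),
                            apoptotic_late_frac = 0.5,
                            annexin_ring_width_um = 1.5,
                            live_lobe_radius_frac = 0.7,
                            live_lobe_offset_frac = 0.45) {
  if (diff(range(net_area_factor_range)) < 0 ||
      min(net_area_factor_range) <= 1) {
    ns_stop("net_area_factor_range must lie above 1", "netscan_param_error")
  }
  defaults <- list(
    ch1_live = 12000, ch1_net = 6000, ch1_necrotic = 16000,
    ch1_apoptotic = 16000,
    ch2_net = 8000, ch2_necrotic = 12000, ch2_apoptotic_late = 10000,
    annexin_ring = 10000, annexin_puncta = 6000
  )
  intensity <- utils::modifyList(defaults, intensity)
  structure(
    list(
      field_px = as.integer(field_px),
      pixel_size_um = pixel_size_um,
      bit_depth = as.integer(bit_depth),
      nuclear_radius_um = nuclear_radius_um,
      net_area_factor_range = net_area_factor_range,
      min_spacing_um = min_spacing_um,
      psf_sigma_um = psf_sigma_um,
      background_level = background_level,
      background_gradient = background_gradient,
      read_noise_sd = read_noise_sd,
      shot_noise_scale = shot_noise_scale,
      intensity = intensity,
      apoptotic_late_frac = apoptotic_late_frac,
      annexin_ring_width_um = annexin_ring_width_um,
      live_lobe_radius_frac = live_lobe_radius_frac,
      live_lobe_offset_frac = live_lobe_offset_frac
    ),
    class = "phenotype_model"
  )
}

# draw per-cell states multinomially so replicate wells show realistic
# sampling variance in their realized class fractions (the total cell
# count is exact; only the composition varies)
#' @noRd
sample_states <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    ns_stop("class fractions must sum to 1", "netscan_param_error")
  }
  if (n == 0L) return(character(0))
  sample(names(fractions), n, replace = TRUE, prob = fractions)
}

# sample n cell centers (px, 1-based) with minimum spacing and margin
#' @noRd
sample_centers <- function(n, field_px, min_spacing_px, margin_px) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  lo <- margin_px; hi <- field_px - margin_px
  if (hi <= lo) {
    ns_stop("field too small for the requested margin", "netscan_param_error")
  }
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 400L * n
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    p <- stats::runif(2, lo, hi)
    if (placed == 0L ||
        min((centers[seq_len(placed), 1] - p[1])^2 +
              (centers[seq_len(placed), 2] - p[2])^2) >=
          min_spacing_px^2) {
      placed <- placed + 1L
      centers[placed, ] <- p
    }
  }
  if (placed < n) {
    ns_stop("could not place all cells: density too high for min spacing",
            "netscan_param_error")
  }
  centers
}

# add a radial sprite into canvases around center (r0, c0)
#' @noRd
sprite_window <- function(field_px, r0, c0, radius_px) {
  w <- as.integer(ceiling(radius_px)) + 2L
  rr <- max(1L, as.integer(floor(r0)) - w):min(field_px,
                                               as.integer(ceiling(r0)) + w)
  cc <- max(1L, as.integer(floor(c0)) - w):min(field_px,
                                               as.integer(ceiling(c0)) + w)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  list(rr = rr, cc = cc, d = sqrt(d2))
}

# render one cell's ideal sprites; returns list of per-channel additive
# patches plus the ground-truth footprint
#' @noRd
render_cell <- function(state, r0, c0, model, four_channel) {
  psz <- model$pixel_size_um
  r_nuc <- model$nuclear_radius_um / psz
  I <- model$intensity
  fp <- model$field_px
  out <- list(sub_state = state, area_factor = 1)

  if (state == "LIVE") {
    k <- sample(2:4, 1)
    lobe_r <- r_nuc * model$live_lobe_radius_frac * stats::runif(k, 0.9, 1.1)
    ang <- stats::runif(k, 0, 2 * pi)
    off <- r_nuc * model$live_lobe_offset_frac
    amp <- I$ch1_live * stats::runif(1, 0.85, 1.15)
    win <- sprite_window(fp, r0, c0, r_nuc * 1.5)
    mask <- matrix(FALSE, length(win$rr), length(win$cc))
    for (j in seq_len(k)) {
      dj <- outer((win$rr - (r0 + off * cos(ang[j])))^2,
                  (win$cc - (c0 + off * sin(ang[j])))^2, "+")
      mask <- mask | dj <= lobe_r[j]^2
    }
    out$ch1 <- list(win = win, vals = amp * mask)
    out$footprint <- list(win = win, mask = mask)
  } else if (state == "NET") {
    f <- stats::runif(1, model$net_area_factor_range[1],
                      model$net_area_factor_range[2])
    out$area_factor <- f
    R <- r_nuc * sqrt(f)
    win <- sprite_window(fp, r0, c0, R)
    mask <- win$d <= R
    prof <- exp(-win$d^2 / (2 * (R / 2)^2)) * mask
    out$ch2 <- list(win = win, vals = I$ch2_net * prof)
    out$ch1 <- list(win = win, vals = I$ch1_net * mask)
    out$footprint <- list(win = win, mask = mask)
    if (four_channel) {
      # disintegrated, punctate Annexin over the cloud
      np <- 6L
      pr <- stats::runif(np, 0, 0.8 * R)
      pa <- stats::runif(np, 0, 2 * pi)
      vals <- matrix(0, length(win$rr), length(win$cc))
      for (j in seq_len(np)) {
        dj <- outer((win$rr - (r0 + pr[j] * cos(pa[j])))^2,
                    (win$cc - (c0 + pr[j] * sin(pa[j])))^2, "+")
        vals[dj <= 1.5^2] <- I$annexin_puncta
      }
      out$annexin <- list(win = win, vals = vals)
    }
  } else if (state == "NECROTIC") {
    r <- r_nuc * 0.7
    win <- sprite_window(fp, r0, c0, r)
    mask <- win$d <= r
    out$ch1 <- list(win = win, vals = I$ch1_necrotic * mask)
    out$ch2 <- list(win = win, vals = I$ch2_necrotic * mask)
    out$footprint <- list(win = win, mask = mask)
  } else if (state == "APOPTOTIC") {
    r <- r_nuc * 0.75
    late <- stats::runif(1) < model$apoptotic_late_frac
    out$sub_state <- if (late) "APOPTOTIC_LATE" else "APOPTOTIC_EARLY"
    ring_w <- model$annexin_ring_width_um / psz
    win <- sprite_window(fp, r0, c0, r + ring_w + 1)
    mask <- win$d <= r
    out$ch1 <- list(win = win, vals = I$ch1_apoptotic * mask)
    if (late) out$ch2 <- list(win = win, vals = I$ch2_apoptotic_late * mask)
    if (four_channel) {
      ring <- win$d > r & win$d <= r + ring_w
      out$annexin <- list(win = win, vals = I$annexin_ring * ring)
    }
    out$footprint <- list(win = win, mask = mask)
  } else {
    ns_stop(paste("unknown phenotype state:", state), "netscan_param_error")
  }
  out
}

#' @noRd
add_patch <- function(canvas, patch) {
  if (is.null(patch)) return(canvas)
  canvas[patch$win$rr, patch$win$cc] <-
    canvas[patch$win$rr, patch$win$cc] + patch$vals
  canvas
}

# blur + background + noise on one ideal canvas -> quantized pixels
#' @noRd
camera <- function(ideal, model) {
  fp <- model$field_px
  maxv <- 2^model$bit_depth - 1
  sigma_px <- model$psf_sigma_um / model$pixel_size_um
  img <- gaussian_smooth_px(ideal, sigma_px)
  grad <- matrix(rep(seq(0, 1, length.out = fp), each = fp), fp, fp)
  img <- img + model$background_level + model$background_gradient * grad
  noise <- stats::rnorm(length(img)) *
    sqrt(pmax(img, 0)) * model$shot_noise_scale +
    stats::rnorm(length(img)) * model$read_noise_sd
  img <- img + matrix(noise, fp, fp)
  matrix(pmin(pmax(round(img), 0), maxv), fp, fp)
}

#' Generate one synthetic field with ground truth
#'
#' @param n_cells number of cells to place (exact).
#' @param class_fractions named numeric vector over
#'   `c("LIVE","NET","NECROTIC","APOPTOTIC")` (subset allowed), summing
#'   to 1. Each cell's state is drawn independently with these
#'   probabilities, so the realized composition varies multinomially
#'   between fields — replicate wells show realistic sampling variance.
#' @param model a [phenotype_model].
#' @param seed integer seed; identical calls are bit-identical.
#' @param well_id,field_index,time_point_min metadata stamped on the
#'   output field.
#' @param four_channel also render the Annexin channel.
#' @return list with `field` (a [field_image]), and `truth`: per-cell
#'   data.frame (`cell_id`, `state`, `sub_state`, `center_row/col`
#'   0-based px, `area_factor`), `label_mask` (a [labeled_mask] of
#'   ground-truth footprints) and `fractions` (true class fractions).
#' @export
generate_field <- function(n_cells, class_fractions, model = phenotype_model(),
                           seed = 1L, well_id = "A01", field_index = 1L,
                           time_point_min = 0, four_channel = FALSE) {
  states_all <- c("LIVE", "NET", "NECROTIC", "APOPTOTIC")
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% states_all)) {
    ns_stop("class_fractions must be named over LIVE/NET/NECROTIC/APOPTOTIC",
            "netscan_param_error")
  }
  with_seed(seed, {
    states <- sample_states(n_cells, class_fractions)
    psz <- model$pixel_size_um
    margin_um <- model$nuclear_radius_um *
      sqrt(max(model$net_area_factor_range)) + 3 * model$psf_sigma_um + 2
    centers <- sample_centers(
      n_cells, model$field_px,
      min_spacing_px = model$min_spacing_um / psz,
      margin_px = ceiling(margin_um / psz)
    )
    fp <- model$field_px
    ch1 <- matrix(0, fp, fp)
    ch2 <- matrix(0, fp, fp)
    ann <- if (four_channel) matrix(0, fp, fp) else NULL
    gt_labels <- matrix(0L, fp, fp)
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      cell <- render_cell(states[i], centers[i, 1], centers[i, 2],
                          model, four_channel)
      ch1 <- add_patch(ch1, cell$ch1)
      ch2 <- add_patch(ch2, cell$ch2)
      if (four_channel) ann <- add_patch(ann, cell$annexin)
      fpm <- cell$footprint
      sub <- gt_labels[fpm$win$rr, fpm$win$cc]
      sub[fpm$mask & sub == 0L] <- i
      gt_labels[fpm$win$rr, fpm$win$cc] <- sub
      truth[[i]] <- data.frame(
        cell_id = i, state = states[i], sub_state = cell$sub_state,
        center_row = centers[i, 1] - 1, center_col = centers[i, 2] - 1,
        area_factor = cell$area_factor, stringsAsFactors = FALSE
      )
    }
    maxI <- 2^model$bit_depth - 1
    channels <- list(
      NUCLEUS_ALL = channel_image(camera(ch1, model), model$bit_depth,
                                  "NUCLEUS_ALL", psz),
      IMPERMEABLE_DNA = channel_image(camera(ch2, model), model$bit_depth,
                                      "IMPERMEABLE_DNA", psz)
    )
    if (four_channel) {
      channels$ANNEXIN <- channel_image(camera(ann, model), model$bit_depth,
                                        "ANNEXIN", psz)
    }
    truth_df <- if (n_cells > 0) do.call(rbind, truth) else
      data.frame(cell_id = integer(0), state = character(0),
                 sub_state = character(0), center_row = numeric(0),
                 center_col = numeric(0), area_factor = numeric(0))
    frac <- if (n_cells > 0) table(factor(truth_df$state, states_all)) / n_cells
    else table(factor(character(0), states_all))
    list(
      field = field_image(channels, well_id = well_id,
                          field_index = field_index,
                          time_point_min = time_point_min),
      truth = truth_df,
      label_mask = labeled_mask(relabel_dense(gt_labels)),
      gt_labels = gt_labels,
      fractions = frac
    )
  })
}

#' Generate a scripted synthetic time-lapse series
#'
#' Per-cell trajectories follow the observed death sequences: necrosis
#' shows dye permeability from an onset sampled in 30-60 min with the
#' nuclear area staying constant; NETosis becomes permeable between 60
#' and 120 min and its dye-positive area grows monotonically to the
#' sampled decondensation factor over 3-5 frames; live cells never become
#' permeable. Cells are immobile up to < 2 um/frame jitter.
#'
#' @param n_cells number of cells.
#' @param fate_fractions named over `c("LIVE","NETOSIS","NECROSIS")`,
#'   summing to 1; per-cell fates are drawn with these probabilities.
#' @param frames strictly increasing acquisition times (minutes).
#' @param model a [phenotype_model].
#' @param seed integer seed.
#' @param well_id metadata for the rendered frames.
#' @param four_channel also render the Annexin channel.
#' @return list with `fields` (list of [field_image], one per frame) and
#'   `truth`: per-cell fates plus a per-frame state table
#'   (`cell_id`, `time_point_min`, `state`, `permeable`, `area_factor`).
#' @export
generate_timelapse <- function(n_cells, fate_fractions, frames,
                               model = phenotype_model(), seed = 1L,
                               well_id = "A01", four_channel = FALSE) {
  if (any(diff(frames) <= 0)) {
    ns_stop("frames must be strictly increasing", "netscan_param_error")
  }
  fates_all <- c("LIVE", "NETOSIS", "NECROSIS")
  if (is.null(names(fate_fractions)) ||
      !all(names(fate_fractions) %in% fates_all)) {
    ns_stop("fate_fractions must be named over LIVE/NETOSIS/NECROSIS",
            "netscan_param_error")
  }
  with_seed(seed, {
    fates <- sample_states(n_cells, fate_fractions)
    psz <- model$pixel_size_um
    margin_um <- model$nuclear_radius_um *
      sqrt(max(model$net_area_factor_range)) + 3 * model$psf_sigma_um + 2
    centers <- sample_centers(
      n_cells, model$field_px,
      min_spacing_px = model$min_spacing_um / psz,
      margin_px = ceiling(margin_um / psz)
    )
    dt <- stats::median(diff(frames))
    onset <- numeric(n_cells)
    growth_min <- numeric(n_cells)
    final_factor <- rep(1, n_cells)
    for (i in seq_len(n_cells)) {
      if (fates[i] == "NECROSIS") {
        onset[i] <- stats::runif(1, 30, 60)
      } else if (fates[i] == "NETOSIS") {
        onset[i] <- stats::runif(1, 60, 120)
        growth_min[i] <- sample(3:5, 1) * dt
        final_factor[i] <- stats::runif(1, model$net_area_factor_range[1],
                                        model$net_area_factor_range[2])
      } else {
        onset[i] <- Inf
      }
    }
    jitter_per_frame <- lapply(seq_along(frames), function(k) {
      if (k == 1) matrix(0, n_cells, 2)
      else {
        a <- stats::runif(n_cells, 0, 2 * pi)
        r <- stats::runif(n_cells, 0, 1) / psz  # < 2 um/frame
        cbind(r * cos(a), r * sin(a))
      }
    })
    fields <- vector("list", length(frames))
    per_frame <- vector("list", length(frames))
    pos <- centers
    for (k in seq_along(frames)) {
      t <- frames[k]
      pos <- pos + jitter_per_frame[[k]]
      fp <- model$field_px
      ch1 <- matrix(0, fp, fp); ch2 <- matrix(0, fp, fp)
      ann <- if (four_channel) matrix(0, fp, fp) else NULL
      rows <- vector("list", n_cells)
      for (i in seq_len(n_cells)) {
        if (t < onset[i]) {
          st <- "LIVE"; af <- 1
        } else if (fates[i] == "NECROSIS") {
          st <- "NECROTIC"; af <- 1
        } else {
          p <- if (growth_min[i] > 0) min(1, (t - onset[i]) / growth_min[i])
          else 1
          af <- 1 + p * (final_factor[i] - 1)
          st <- "NET"
        }
        cell <- render_timelapse_cell(st, af, pos[i, 1], pos[i, 2], model,
                                      four_channel)
        ch1 <- add_patch(ch1, cell$ch1)
        ch2 <- add_patch(ch2, cell$ch2)
        if (four_channel) ann <- add_patch(ann, cell$annexin)
        rows[[i]] <- data.frame(
          cell_id = i, time_point_min = t, state = st,
          permeable = st != "LIVE", area_factor = af,
          center_row = pos[i, 1] - 1, center_col = pos[i, 2] - 1,
          stringsAsFactors = FALSE
        )
      }
      channels <- list(
        NUCLEUS_ALL = channel_image(camera(ch1, model), model$bit_depth,
                                    "NUCLEUS_ALL", psz),
        IMPERMEABLE_DNA = channel_image(camera(ch2, model), model$bit_depth,
                                        "IMPERMEABLE_DNA", psz)
      )
      if (four_channel) {
        channels$ANNEXIN <- channel_image(camera(ann, model),
                                          model$bit_depth, "ANNEXIN", psz)
      }
      fields[[k]] <- field_image(channels, well_id = well_id,
                                 field_index = 1L, time_point_min = t)
      per_frame[[k]] <- do.call(rbind, rows)
    }
    list(
      fields = fields,
      truth = list(
        fates = data.frame(cell_id = seq_len(n_cells), fate = fates,
                           onset_min = onset,
                           final_factor = final_factor,
                           center_row = centers[, 1] - 1,
                           center_col = centers[, 2] - 1,
                           stringsAsFactors = FALSE),
        per_frame = do.call(rbind, per_frame)
      )
    )
  })
}

# deterministic (no extra RNG) rendering of a time-lapse cell so that a
# cell's appearance is a smooth function of its scripted state
#' @noRd
render_timelapse_cell <- function(state, area_factor, r0, c0, model,
                                  four_channel) {
  psz <- model$pixel_size_um
  r_nuc <- model$nuclear_radius_um / psz
  I <- model$intensity
  fp <- model$field_px
  out <- list()
  if (state == "LIVE") {
    win <- sprite_window(fp, r0, c0, r_nuc)
    mask <- win$d <= r_nuc
    out$ch1 <- list(win = win, vals = I$ch1_live * mask)
  } else if (state == "NECROTIC") {
    r <- r_nuc * 0.7
    win <- sprite_window(fp, r0, c0, r)
    mask <- win$d <= r
    out$ch1 <- list(win = win, vals = I$ch1_necrotic * mask)
    out$ch2 <- list(win = win, vals = I$ch2_necrotic * mask)
  } else {  # NET at the current decondensation factor
    R <- r_nuc * sqrt(area_factor)
    win <- sprite_window(fp, r0, c0, R)
    mask <- win$d <= R
    prof <- exp(-win$d^2 / (2 * (R / 2)^2)) * mask
    out$ch2 <- list(win = win, vals = I$ch2_net * prof)
    out$ch1 <- list(win = win, vals = I$ch1_net * mask)
  }
  out
}
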