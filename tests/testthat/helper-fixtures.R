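# Programmatic fixtures shared across test files.

PSZ <- 0.65  # um/px used throughout the fixtures

# matrix with filled discs; centers is a matrix of (row, col), values
# recycled per disc
disc_matrix <- function(nr, nc, centers, radii, values = 1000, base = 0) {
  m <- matrix(base, nr, nc)
  values <- rep(values, length.out = nrow(centers))
  radii <- rep(radii, length.out = nrow(centers))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
    m[d2 <= radii[i]^2] <- values[i]
  }
  m
}

nucleus_channel <- function(pixels, pixel_size_um = PSZ) {
  channel_image(pixels, bit_depth = 16L, channel_role = "NUCLEUS_ALL",
                pixel_size_um = pixel_size_um)
}

dna_dye_channel <- function(pixels, pixel_size_um = PSZ) {
  channel_image(pixels, bit_depth = 16L, channel_role = "IMPERMEABLE_DNA",
                pixel_size_um = pixel_size_um)
}

# random non-touching disc image: boundary separation >= 2 px guaranteed
random_disc_image <- function(n_discs, size = 128, r_range = c(4, 8),
                              margin = 12) {
  radii <- numeric(0); centers <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(centers) < n_discs && guard < 5000) {
    guard <- guard + 1
    r <- runif(1, r_range[1], r_range[2])
    p <- runif(2, margin, size - margin)
    ok <- TRUE
    if (nrow(centers)) {
      d <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
      ok <- all(d >= radii + r + 4)  # >= 2 px of background between discs
    }
    if (ok) {
      centers <- rbind(centers, p)
      radii <- c(radii, r)
    }
  }
  list(
    pixels = disc_matrix(size, size, centers, radii, values = 5000),
    centers = centers, radii = radii
  )
}

# minimal feature records for classification tests
make_records <- function(avg_intensity_ch2, target_area_ch2_um2,
                         area_ch1_um2 = 40, well_id = "A01",
                         annexin_ring_ratio = NA_real_,
                         annexin_cv = NA_real_) {
  n <- max(length(avg_intensity_ch2), length(target_area_ch2_um2))
  data.frame(
    object_id = seq_len(n),
    well_id = rep(well_id, length.out = n),
    field_index = rep(1L, n),
    time_point_min = rep(0, n),
    centroid_row = rep(0, n), centroid_col = rep(0, n),
    area_ch1_um2 = rep(area_ch1_um2, length.out = n),
    target_area_ch2_um2 = rep(target_area_ch2_um2, length.out = n),
    avg_intensity_ch2 = rep(avg_intensity_ch2, length.out = n),
    avg_intensity_ch1 = rep(1000, n),
    annexin_ring_ratio = rep(annexin_ring_ratio, length.out = n),
    annexin_cv = rep(annexin_cv, length.out = n),
    border = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

two_well_layout <- function(fields_per_well = 1L, mode = "TWO_CHANNEL",
                            time_series = NULL) {
  plate_layout(
    data.frame(
      well_id = c("A01", "B01"),
      treatment = c("control", "PMA"),
      concentration = c(0, 100),
      units = "nM",
      role = c("CONTROL", "STIMULATED"),
      stringsAsFactors = FALSE
    ),
    fields_per_well = fields_per_well, mode = mode,
    pixel_size_um = PSZ, time_series = time_series
  )
}

# small, fast phenotype model for unit tests
small_model <- function(...) {
  phenotype_model(field_px = 384L, ...)
}

# generate a plate of synthetic fields plus pooled ground truth
synthetic_plate <- function(layout, fracs_by_well, n_cells, model,
                            seed0 = 1L, four_channel = FALSE) {
  fields <- list(); truths <- list(); gtl <- list()
  for (wi in seq_len(nrow(layout$wells))) {
    w <- layout$wells$well_id[wi]
    for (f in seq_len(layout$fields_per_well)) {
      g <- generate_field(n_cells, fracs_by_well[[wi]], model,
                          seed = seed0 + 131L * wi + f, well_id = w,
                          field_index = f, four_channel = four_channel)
      tag <- sprintf("%s_f%02d", w, f)
      fields[[tag]] <- g$field
      tr <- g$truth
      if (nrow(tr)) { tr$well_id <- w; tr$field_index <- f }
      truths[[tag]] <- tr
      gtl[[tag]] <- g$gt_labels
    }
  }
  list(fields = unname(fields), truth = truths, gt_labels = gtl)
}

# majority-overlap matching of detected nuclei to ground-truth cells
match_to_truth <- function(nuclei_labels, gt_labels) {
  vapply(seq_len(max(0L, max(nuclei_labels))), function(i) {
    v <- gt_labels[nuclei_labels == i]
    v <- v[v > 0]
    if (!length(v)) NA_integer_
    else as.integer(names(sort(table(v), decreasing = TRUE))[1])
  }, integer(1))
}

# per-class F1 from aligned truth/prediction character vectors
class_f1 <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}
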