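test_that("field TIFF round-trip preserves pixel values bit-exactly", {
  set.seed(11)
  px1 <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64, 64)
  px2 <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64, 64)
  px3 <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64, 64)
  fld <- field_image(
    list(
      NUCLEUS_ALL = nucleus_channel(px1),
      IMPERMEABLE_DNA = dna_dye_channel(px2),
      OTHER = channel_image(px3, 16L, "OTHER", PSZ)
    ),
    well_id = "B02", field_index = 3L, time_point_min = 45
  )
  dir <- withr::local_tempdir()
  paths <- write_field(fld, dir)
  back <- read_field(paths, well_id = "B02", field_index = 3L,
                     time_point_min = 45, pixel_size_um = PSZ)
  expect_setequal(names(back$channels), names(fld$channels))
  for (role in names(fld$channels)) {
    expect_identical(back$channels[[role]]$pixels + 0,
                     fld$channels[[role]]$pixels + 0)
  }
  expect_equal(back$well_id, "B02")
  expect_equal(back$field_index, 3L)
})

test_that("field construction enforces channel invariants", {
  a <- nucleus_channel(matrix(0, 32, 32))
  b_small <- dna_dye_channel(matrix(0, 16, 16))
  expect_error(field_image(list(NUCLEUS_ALL = a, IMPERMEABLE_DNA = b_small),
                           "A01"),
               class = "netscan_dim_error")
  expect_error(field_image(list(IMPERMEABLE_DNA = dna_dye_channel(matrix(0, 32, 32))),
                           "A01"),
               class = "netscan_config_error")
  expect_error(channel_image(matrix(-1, 4, 4)), class = "netscan_type_error")
  expect_error(channel_image(matrix(300, 4, 4), bit_depth = 8L),
               class = "netscan_type_error")
})

test_that("plate layout loads from YAML and rejects duplicate wells", {
  cfg <- list(
    mode = "TWO_CHANNEL",
    pixel_size_um = 0.65,
    fields_per_well = 2,
    wells = list(
      list(well_id = "A01", treatment = "control", concentration = 0,
           units = "nM", role = "CONTROL"),
      list(well_id = "A02", treatment = "PMA", concentration = 100,
           units = "nM", role = "STIMULATED")
    )
  )
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  lay <- load_plate_layout(f)
  expect_equal(nrow(lay$wells), 2L)
  expect_equal(lay$wells$role, c("CONTROL", "STIMULATED"))

  cfg$wells[[2]]$well_id <- "A01"
  yaml::write_yaml(cfg, f)
  expect_error(load_plate_layout(f), class = "netscan_config_error")

  cfg$wells[[2]]$well_id <- "A02"
  cfg$time_series <- seq(0, 180, by = 15)
  yaml::write_yaml(cfg, f)
  lay <- load_plate_layout(f)
  expect_length(lay$time_series, 13L)
})

test_that("layout validation catches missing image files", {
  lay <- two_well_layout()
  cfg <- list(
    mode = "TWO_CHANNEL", pixel_size_um = 0.65, fields_per_well = 1,
    wells = list(
      list(well_id = "A01", treatment = "c", concentration = 0,
           units = "", role = "CONTROL")
    )
  )
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  empty_dir <- withr::local_tempdir()
  expect_error(load_plate_layout(f, image_dir = empty_dir),
               "missing image", class = "netscan_config_error")
})

test_that("write_results writes tables, masks and a consistent manifest", {
  dir <- withr::local_tempdir()
  # empty run: header-only tables, zero counts
  empty <- make_records(numeric(0), numeric(0))
  man <- write_results(empty, empty[0, c("well_id", "object_id")],
                       out_dir = dir)
  expect_equal(man$files$objects$n_rows, 0L)
  tab <- utils::read.csv(file.path(dir, "objects.csv"))
  expect_equal(nrow(tab), 0L)

  # populated run with a 300-label mask
  rec <- make_records(runif(100, 0, 2000), runif(100, 0, 300),
                      well_id = rep(c("A01", "B01"), each = 50))
  summ <- rbind(
    summarize_well(rec[1:50, ], rep("TYPE3_LIVE", 50), "A01"),
    summarize_well(rec[51:100, ], rep("TYPE1_NET", 50), "B01")
  )
  labs <- matrix(0L, 64, 64)
  labs[cbind(sample(2:63, 300, TRUE), sample(2:63, 300, TRUE))] <- 0L
  # deterministic dense mask with 300 single-pixel objects
  pos <- head(which(labs == 0L), 300)
  labs[pos] <- seq_len(300)
  mask <- labeled_mask(labs)
  man <- write_results(rec, summ, masks = list(A01_f01 = mask),
                       out_dir = dir)
  expect_equal(man$files$objects$n_rows, 100L)
  expect_equal(man$files$well_summary$n_rows, 2L)
  back <- utils::read.csv(file.path(dir, "objects.csv"))
  expect_equal(back$avg_intensity_ch2, rec$avg_intensity_ch2)
  mask_back <- read_mask(file.path(dir, "masks", "A01_f01_mask.tif"))
  expect_identical(mask_back$labels, mask$labels)
  expect_equal(mask_back$n_objects, 300L)
})
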