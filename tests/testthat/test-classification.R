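ctrl_layout <- function() {
  plate_layout(data.frame(
    well_id = c("A01", "B01"), treatment = c("control", "stim"),
    concentration = c(0, 1), units = "uM",
    role = c("CONTROL", "STIMULATED"), stringsAsFactors = FALSE
  ))
}

test_that("bimodal intensity split lands between the two populations", {
  set.seed(42)
  ctrl_int <- rnorm(700, 100, 10)
  stim_int <- rnorm(300, 1000, 100)
  rec <- rbind(
    make_records(ctrl_int, 10, area_ch1_um2 = 40, well_id = "A01"),
    make_records(stim_int, 200, area_ch1_um2 = 40, well_id = "B01")
  )
  refs <- estimate_reference_levels(rec, ctrl_layout())
  expect_gt(refs$intensity_ref, 200)
  expect_lt(refs$intensity_ref, 800)
  expect_equal(refs$provenance, "AUTO")
  # brute-force between-class-variance scan over the sorted sample
  expect_equal(refs$intensity_ref,
               brute_split_1d(rec$avg_intensity_ch2), tolerance = 1e-12)
})

test_that("area gate is the multiplier times the control median", {
  set.seed(8)
  areas <- c(rep(40, 101))  # median exactly 40
  rec <- rbind(
    make_records(rnorm(101, 100, 5), 10, area_ch1_um2 = areas,
                 well_id = "A01"),
    make_records(rnorm(60, 1500, 50), 300, well_id = "B01")
  )
  refs <- estimate_reference_levels(rec, ctrl_layout())
  expect_equal(refs$area_ref_um2, 2 * 40)
  refs3 <- estimate_reference_levels(rec, ctrl_layout(),
                                     area_multiplier = 3)
  expect_equal(refs3$area_ref_um2, 3 * 40)
})

test_that("unimodal plates fall back to median + 5 MAD of controls", {
  set.seed(9)
  intensities <- rnorm(400, 120, 15)  # no stimulated population
  rec <- make_records(intensities, 5, well_id = "A01")
  refs <- estimate_reference_levels(rec, ctrl_layout())
  expect_equal(refs$intensity_ref,
               median(intensities) + 5 * mad(intensities),
               tolerance = 1e-12)
})

test_that("estimation refuses with too few control objects", {
  rec <- make_records(rnorm(30, 100, 10), 5, well_id = "A01")
  expect_error(estimate_reference_levels(rec, ctrl_layout()),
               class = "netscan_estimation_error")
  no_ctrl <- plate_layout(data.frame(
    well_id = "B01", treatment = "stim", concentration = 1, units = "uM",
    role = "STIMULATED", stringsAsFactors = FALSE
  ))
  expect_error(estimate_reference_levels(rec, no_ctrl),
               class = "netscan_estimation_error")
})

test_that("two-channel gates implement the three event definitions", {
  refs <- reference_levels(intensity_ref = 400, area_ref_um2 = 100)
  cases <- data.frame(
    int = c(2, 2, 0.5, 1) * 400,
    area = c(3, 0.5, 10, 1) * 100,
    expect = c("TYPE1_NET", "TYPE2_OTHER_DEATH", "TYPE3_LIVE", "TYPE1_NET")
  )
  rec <- make_records(cases$int, cases$area)
  expect_equal(classify_two_channel(rec, refs), cases$expect)
})

test_that("two-channel classes match the boolean truth table everywhere", {
  refs <- reference_levels(intensity_ref = 300, area_ref_um2 = 80)
  set.seed(13)
  rec <- make_records(runif(5000, 0, 600), runif(5000, 0, 160))
  got <- classify_two_channel(rec, refs)
  oracle <- ifelse(
    rec$avg_intensity_ch2 >= 300 & rec$target_area_ch2_um2 >= 80,
    "TYPE1_NET",
    ifelse(rec$avg_intensity_ch2 >= 300, "TYPE2_OTHER_DEATH", "TYPE3_LIVE")
  )
  expect_identical(got, oracle)
  # exactly one class per cell
  expect_true(all(got %in% c("TYPE1_NET", "TYPE2_OTHER_DEATH",
                             "TYPE3_LIVE")))
})

test_that("gate monotonicity moves cells only along the allowed edges", {
  set.seed(14)
  rec <- make_records(runif(2000, 0, 800), runif(2000, 0, 300))
  refs_lo <- reference_levels(intensity_ref = 300, area_ref_um2 = 80)
  refs_hi_area <- reference_levels(intensity_ref = 300, area_ref_um2 = 150)
  a <- classify_two_channel(rec, refs_lo)
  b <- classify_two_channel(rec, refs_hi_area)
  moved <- a != b
  expect_true(all(a[moved] == "TYPE1_NET" & b[moved] == "TYPE2_OTHER_DEATH"))
  # raising I* can only grow the live pool
  refs_hi_int <- reference_levels(intensity_ref = 500, area_ref_um2 = 80)
  c3 <- classify_two_channel(rec, refs_hi_int)
  expect_true(all(c3[a == "TYPE3_LIVE"] == "TYPE3_LIVE"))
  expect_gte(sum(c3 == "TYPE3_LIVE"), sum(a == "TYPE3_LIVE"))
})

test_that("four-channel gates resolve NET, necrosis and apoptosis", {
  refs <- reference_levels(intensity_ref = 400, area_ref_um2 = 100,
                           annexin_ring_ref = 2)
  rec <- make_records(
    avg_intensity_ch2 = c(800, 800, 100, 100),
    target_area_ch2_um2 = c(400, 40, 30, 20),
    annexin_ring_ratio = c(1.2, 0.9, 3.5, 1.0),
    annexin_cv = c(1.5, 0.2, 0.3, 0.1)
  )
  expect_equal(classify_four_channel(rec, refs),
               c("NET", "NECROTIC", "APOPTOTIC", "LIVE"))
  # late apoptosis: PI positive but surface annexin dominates
  late <- make_records(800, 40, annexin_ring_ratio = 3.0, annexin_cv = 0.2)
  expect_equal(classify_four_channel(late, refs), "APOPTOTIC")
  # missing annexin features is a configuration error
  expect_error(classify_four_channel(make_records(800, 40), refs),
               class = "netscan_config_error")
})
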