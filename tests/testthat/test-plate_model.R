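test_that("a full 384-well layout joins its readout into a complete plate", {
  cfg <- sim_config(seed = 3, n_drugs = 16, plate_failure_rate = 0)
  set.seed(3)
  prof <- simulate_patient_profile(cfg)
  plate <- simulate_plate(cfg, prof, failed = FALSE)
  expect_s3_class(plate, "fpm_plate")
  expect_identical(nrow(plate$wells), 384L)

  dir <- withr::local_tempdir()
  write_plate(plate, file.path(dir, "l.csv"), file.path(dir, "r.csv"),
              file.path(dir, "m.csv"))
  back <- read_plate(file.path(dir, "l.csv"), file.path(dir, "r.csv"),
                     file.path(dir, "m.csv"))
  expect_equal(back$wells$rlu, plate$wells$rlu, tolerance = 1e-12)
  expect_identical(back$wells$well, plate$wells$well)
  expect_identical(back$plate_id, plate$plate_id)
  expect_identical(back$patient_id, plate$patient_id)
  expect_identical(back$cancer_class, plate$cancer_class)
  expect_identical(back$received_date, plate$received_date)
  expect_identical(back$readout_date, plate$readout_date)
  # empty wells carry absent luminescence after the round trip
  expect_true(all(is.na(back$wells$rlu[back$wells$content == "empty"])))
})

test_that("malformed layouts and readouts are rejected with specific errors", {
  dir <- withr::local_tempdir()
  lay <- data.frame(well = c("P24", "P24"), content = "negative_control",
                    drug_id = NA, concentration_uM = NA, replicate = 1)
  write.csv(lay, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(read_plate(file.path(dir, "dup.csv")), "duplicate well")

  lay2 <- data.frame(well = c("A1", "A2"), content = "negative_control",
                     drug_id = NA, concentration_uM = NA, replicate = 1)
  write.csv(lay2, file.path(dir, "l.csv"), row.names = FALSE)
  write.csv(data.frame(well = "A1", rlu = -5), file.path(dir, "neg.csv"),
            row.names = FALSE)
  expect_error(read_plate(file.path(dir, "l.csv"), file.path(dir, "neg.csv")),
               "negative RLU")

  write.csv(data.frame(well = "B9", rlu = 10), file.path(dir, "orphan.csv"),
            row.names = FALSE)
  expect_error(read_plate(file.path(dir, "l.csv"), file.path(dir, "orphan.csv")),
               "missing from layout")

  # drug wells must carry a positive dose and an id
  expect_error(fpm_plate(data.frame(well = "A1", content = "drug_dose",
                                    drug_id = "a", concentration_uM = -1,
                                    replicate = 1, rlu = NA)),
               "positive concentration")
  expect_error(fpm_plate(data.frame(well = "A1", content = "drug_dose",
                                    drug_id = NA, concentration_uM = 1,
                                    replicate = 1, rlu = NA)),
               "drug_id")
})

test_that("an empty-well-only plate round-trips with zero dose series", {
  wells <- data.frame(well = c("A1", "A2", "B1"), content = "empty",
                      drug_id = NA, concentration_uM = NA, replicate = 1,
                      rlu = NA)
  plate <- fpm_plate(wells)
  dir <- withr::local_tempdir()
  write_plate(plate, file.path(dir, "l.csv"))
  back <- read_plate(file.path(dir, "l.csv"))
  expect_identical(back$wells$content, plate$wells$content)
  expect_length(extract_dose_series(back), 0L)
})

test_that("combination drug ids survive the round trip and split into agents", {
  combo <- combination_id(c("topotecan", "cyclophosphamide"))
  expect_identical(combo, "cyclophosphamide+topotecan")
  plate <- make_mini_plate(setNames(list(rep(50, 10)), combo))
  dir <- withr::local_tempdir()
  write_plate(plate, file.path(dir, "l.csv"), file.path(dir, "r.csv"))
  back <- read_plate(file.path(dir, "l.csv"), file.path(dir, "r.csv"))
  series <- extract_dose_series(back)
  expect_identical(series[[1]]$drug_id, combo)
  expect_identical(series[[1]]$agents, c("cyclophosphamide", "topotecan"))
})

test_that("series extraction partitions drug wells and sorts concentrations", {
  plate <- make_mini_plate(list(drugA = seq(0, 90, length.out = 10),
                                drugB = rep(5, 10)))
  series <- extract_dose_series(plate)
  expect_length(series, 2L)
  expect_identical(nrow(series$drugA$wells), 20L)
  expect_length(series$drugA$concentrations, 10L)
  expect_false(series$drugA$insufficient)

  # partition: every drug well lands in exactly one series
  all_wells <- unlist(lapply(series, function(s) s$wells$well))
  drug_wells <- plate$wells$well[plate$wells$content == "drug_dose"]
  expect_setequal(all_wells, drug_wells)
  expect_identical(anyDuplicated(all_wells), 0L)

  # ordering invariant under row shuffling of the input
  set.seed(8)
  shuffled <- plate
  shuffled$wells <- plate$wells[sample(nrow(plate$wells)), ]
  series2 <- extract_dose_series(shuffled)
  expect_identical(series2$drugA$concentrations, series$drugA$concentrations)
  expect_false(is.unsorted(series2$drugA$wells$concentration_uM))
})

test_that("single-concentration drugs are flagged insufficient, not fit", {
  wells <- rbind(
    data.frame(well = c("A1", "A2"), content = "drug_dose", drug_id = "solo",
               concentration_uM = 1, replicate = 1:2, rlu = 5e4),
    data.frame(well = c("B1", "B2", "B3", "B4"),
               content = rep(c("negative_control", "positive_control"), each = 2),
               drug_id = NA, concentration_uM = NA, replicate = 1,
               rlu = c(1e5, 1e5, 2e3, 2e3))
  )
  series <- extract_dose_series(fpm_plate(wells))
  expect_true(series$solo$insufficient)
  curves <- fit_plate(fpm_plate(wells), allow_failed_qc = TRUE)
  expect_null(curves$solo)
})

test_that("the drug library reader validates its schema", {
  dir <- withr::local_tempdir()
  lib <- data.frame(drug_id = c("a", "b"), name = c("A", "B"),
                    class = "cytotoxic", formulary = c(TRUE, FALSE),
                    cmax_uM = c(2, NA))
  write.csv(lib, file.path(dir, "lib.csv"), row.names = FALSE)
  got <- read_drug_library(file.path(dir, "lib.csv"))
  expect_identical(got$drug_id, c("a", "b"))
  expect_true(is.na(got$cmax_uM[2]))

  bad <- rbind(lib, lib[1, ])
  write.csv(bad, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(read_drug_library(file.path(dir, "dup.csv")), "duplicate")
})
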