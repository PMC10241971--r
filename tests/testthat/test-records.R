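test_that("ICD-10 normalization collapses subcodes but keeps D48.5 distinct", {
  expect_equal(normalize_icd("C43.5"), "C43")
  expect_equal(normalize_icd("d03"), "D03")
  expect_equal(normalize_icd("D48.5"), "D48.5")
  expect_equal(normalize_icd("D485"), "D48.5")
  expect_equal(normalize_icd("D48"), "D48")
  expect_equal(normalize_icd("D48.9"), "D48")
  expect_false(normalize_icd("D48.5") == normalize_icd("D48"))
  # unmappable codes surface as NA, never pass through
  expect_true(is.na(normalize_icd("X99")))
  expect_true(is.na(normalize_icd("garbled")))
  expect_true(is.na(normalize_icd("")))
})

test_that("ICD-10 normalization is idempotent on every known category", {
  cases <- c("C43.5", "d03", "D485", "D48", "D22.9", "L82", "d21", "D18.0")
  once <- normalize_icd(cases)
  expect_equal(normalize_icd(once), once)
})

test_that("morphology codes map to melanoma categories per the static map", {
  expect_equal(morphology_to_icd("55320002"), "C43")
  expect_equal(morphology_to_icd("2092003"), "C43")
  expect_equal(morphology_to_icd("44474009"), "C43")
  expect_equal(morphology_to_icd("61217001"), "D03")
  expect_equal(morphology_to_icd("77986002"), "D03")
  expect_equal(morphology_to_icd("99999999"), "OTHER")
})

test_that("morphology map agrees with the packaged matched-case listing", {
  ref <- table1_cases()$reference
  expect_equal(nrow(ref), 23L)
  expect_equal(morphology_to_icd(ref$morphology), ref$diagnosis)
})

test_that("location compatibility follows the coarse-site table and wildcard", {
  expect_true(locations_compatible("TORSO_FRONT", "Entire skin of abdomen"))
  expect_true(locations_compatible("TORSO_BACK", "Skin tissue"))
  expect_false(locations_compatible("TORSO_BACK", "Entire skin of abdomen"))
  expect_error(locations_compatible("TORSO_BACK", "Entire skin of mars"),
               "Entire skin of mars")
  # wildcard site is compatible with every region
  expect_true(all(locations_compatible(fine_regions(), "Skin tissue")))
})

test_that("readers parse clean rows, ledger flawed rows, and round-trip", {
  idx <- make_index(c("a", "b", "c"), c("p1", "p2", "p3"),
                    c("2018-01-01", "2018-02-01", "2018-03-01"),
                    c("D22", "C43", "D48.5"),
                    c("NO_ACTION", "EXCISION", "BIOPSY"),
                    c("TORSO_FRONT", "TORSO_BACK", "LEFT_ARM_UP"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_tests(idx, path)
  back <- read_index_tests(path)
  expect_equal(back$records, idx)
  expect_equal(nrow(back$rejects), 0L)

  raw <- idx
  raw$patient_id[2] <- ""
  out <- validate_index_tests(raw)
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$rejects$id, "b")
  expect_match(out$rejects$reason, "matching criterion \\(2\\)")

  ref <- make_reference(c("r1", "r2"), c("p1", "p2"),
                        c("2018-05-01", "2018-06-01"),
                        c("Entire skin of back", "Skin tissue"))
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_reference_tests(ref, rpath)
  rback <- read_reference_tests(rpath)
  expect_equal(rback$records, ref)
})

test_that("reject reasons name the broken matching criterion", {
  raw <- make_index(paste0("c", 1:5), c("p1", "p2", "p3", "p4", "p5"),
                    "2018-01-01", "D22", "NO_ACTION", "TORSO_FRONT")
  raw$exam_date <- as.character(raw$exam_date)
  raw$exam_date[1] <- "02/01/2018"
  raw$region[2] <- "ELBOW"
  raw$diagnosis[3] <- "Z99"
  raw$plan[4] <- "PHONE_CALL"
  out <- validate_index_tests(raw)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$rejects$reason_code,
               c("missing_date", "missing_location", "unknown_diagnosis",
                 "unknown_plan"))
})

test_that("duplicated keys and missing columns are hard errors", {
  idx <- make_index(c("a", "a"), c("p1", "p2"), "2018-01-01", "D22",
                    "NO_ACTION", "TORSO_FRONT")
  expect_error(validate_index_tests(idx), "duplicated case_id")
  expect_error(validate_index_tests(idx[, -2]), "patient_id")
  ref <- make_reference(c("r", "r"), c("p1", "p2"), "2018-01-01",
                        "Skin tissue")
  expect_error(validate_reference_tests(ref), "duplicated record_id")
})

test_that("reference rows with histopathology before excision are rejected", {
  ref <- make_reference("r1", "p1", "2018-05-01", "Skin tissue",
                        excision_offset = -2)
  out <- validate_reference_tests(ref)
  expect_equal(nrow(out$records), 0L)
  expect_equal(out$rejects$reason_code, "date_order")
})
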