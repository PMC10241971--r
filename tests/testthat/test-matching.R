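test_that("candidates satisfy window, patient and location criteria", {
  idx <- make_index(c("a", "b", "c"), c("p1", "p1", "p2"),
                    c("2018-01-01", "2018-01-01", "2018-01-01"),
                    "C43", "EXCISION",
                    c("TORSO_FRONT", "TORSO_BACK", "TORSO_FRONT"))
  ref <- make_reference(c("r1", "r2"), c("p1", "p1"),
                        c("2018-01-11", "2019-12-12"),
                        "Entire skin of abdomen")
  cand <- find_candidates(idx, ref)
  # r2 is 710 days out (beyond the window); b is at an incompatible region;
  # c belongs to another patient
  expect_equal(cand$case_id, "a")
  expect_equal(cand$record_id, "r1")
  expect_equal(cand$gap_days, 10L)

  # two references within the window at compatible sites -> two candidates
  ref2 <- make_reference(c("r1", "r2"), "p1", c("2018-01-11", "2018-02-01"),
                         "Entire skin of abdomen")
  expect_equal(nrow(find_candidates(idx[1, ], ref2)), 2L)

  # window boundary is inclusive
  ref3 <- make_reference("r3", "p1", as.Date("2018-01-01") + 548,
                         "Entire skin of abdomen")
  expect_equal(nrow(find_candidates(idx[1, ], ref3)), 1L)
  ref4 <- make_reference("r4", "p1", as.Date("2018-01-01") + 549,
                         "Entire skin of abdomen")
  expect_equal(nrow(find_candidates(idx[1, ], ref4)), 0L)
})

test_that("consecutive same-lesion examinations keep the earliest", {
  idx <- make_index(c("a", "b"), "p1", c("2018-01-01", "2018-03-01"),
                    "D22", c("NO_ACTION", "EXCISION"), "TORSO_FRONT")
  none <- find_candidates(idx, make_reference(character(), character(),
                                              character(), character())[0, ])
  dd <- dedupe_consecutive(idx, none)
  expect_equal(dd$kept, "a")
  expect_equal(dd$exclusions$id, "b")
  expect_equal(dd$exclusions$reason_code, "later_duplicate_index")
})

test_that("a first checkup examination without a reference candidate yields", {
  idx <- make_index(c("a", "b"), "p1", c("2018-01-01", "2018-07-10"),
                    c("D22", "C43"), c("CHECKUP_6M", "EXCISION"),
                    "TORSO_FRONT")
  ref <- make_reference("r1", "p1", "2018-07-20", "Entire skin of abdomen")
  cand <- find_candidates(idx, ref)
  # both are candidates (within window, compatible): no exception, keep first
  dd <- dedupe_consecutive(idx, cand)
  expect_equal(dd$kept, "a")

  # push the reference outside the first exam's window: the checkup-plan
  # first exam has no candidate and is excluded in favour of the follow-up
  ref2 <- make_reference("r1", "p1", as.Date("2018-01-01") + 560,
                         "Entire skin of abdomen")
  cand2 <- find_candidates(idx, ref2)
  dd2 <- dedupe_consecutive(idx, cand2)
  expect_equal(dd2$kept, "b")
  expect_equal(dd2$exclusions$reason_code, "checkup_first_unmatched")

  # a lone examination is always kept
  dd3 <- dedupe_consecutive(idx[1, ], cand2[0, ])
  expect_equal(dd3$kept, "a")
})

test_that("duplicate references resolve to the least-gap pair", {
  cand <- data.frame(case_id = c("a", "a"), record_id = c("r1", "r2"),
                     patient_id = "p1", gap_days = c(79L, 29L),
                     stringsAsFactors = FALSE)
  out <- resolve_duplicate_references(cand)
  expect_equal(out$record_id, "r2")
  expect_equal(attr(out, "dropped_refs"), "r1")

  single <- cand[1, ]
  expect_equal(resolve_duplicate_references(single)$record_id, "r1")
})

test_that("gap ties break deterministically and do not change the matrix", {
  cand <- data.frame(case_id = c("a", "a"), record_id = c("r2", "r1"),
                     patient_id = "p1", gap_days = c(30L, 30L),
                     stringsAsFactors = FALSE)
  out <- resolve_duplicate_references(cand)
  expect_equal(out$record_id, "r1")
  # exhaustive check: either choice leaves one matched pair for the same
  # index test, so tp/fn are identical whichever record wins the tie
  labels <- c(a = "POSITIVE")
  for (keep in c("r1", "r2")) {
    forced <- cand[cand$record_id == keep, ]
    asg <- resolve_scenario(forced, "WORST_CASE", labels)
    expect_equal(nrow(asg), 1L)
    expect_equal(asg$case_id, "a")
  }
})

test_that("scenario resolution picks the FN extreme on the toy instance", {
  cand <- data.frame(case_id = c("neg", "pos"), record_id = "r1",
                     patient_id = "p1", gap_days = c(10L, 20L),
                     stringsAsFactors = FALSE)
  labels <- c(neg = "NEGATIVE", pos = "POSITIVE")
  worst <- resolve_scenario(cand, "WORST_CASE", labels)
  best <- resolve_scenario(cand, "BEST_CASE", labels)
  expect_equal(worst$case_id, "neg")
  expect_equal(best$case_id, "pos")
})

test_that("scenario extremes equal brute-force enumeration on random instances", {
  set.seed(421)
  for (k in 1:120) {
    inst <- random_instance(max_edges = 8)
    oracle <- brute_force_fn_range(inst$candidates, inst$labels)
    worst <- resolve_scenario(inst$candidates, "WORST_CASE", inst$labels)
    best <- resolve_scenario(inst$candidates, "BEST_CASE", inst$labels)
    fn_of <- function(a) sum(inst$labels[a$case_id] == "NEGATIVE")
    expect_equal(fn_of(worst), unname(oracle["max"]))
    expect_equal(fn_of(best), unname(oracle["min"]))
    expect_gte(fn_of(worst), fn_of(best))
  }
})

test_that("oversized ambiguity components abort with a review request", {
  inst <- random_instance(max_edges = 12)
  while (nrow(inst$candidates) < 3) inst <- random_instance(max_edges = 12)
  expect_error(resolve_scenario(inst$candidates, "WORST_CASE", inst$labels,
                                max_component = 2L),
               "review these records manually")
})

test_that("full matching on the packaged listing yields 22 pairs, 1 duplicate", {
  t1 <- table1_cases()
  mr <- match_records(t1$index, t1$reference)
  expect_equal(nrow(mr$matched_pairs), 22L)
  dup <- mr$exclusion_ledger[mr$exclusion_ledger$reason_code ==
                               "duplicate_diagnosis", ]
  expect_equal(dup$id, "HP15B")
  # patient 15 keeps the least-gap record
  expect_equal(mr$matched_pairs$record_id[mr$matched_pairs$case_id == "TD15"],
               "HP15")
  expect_equal(mr$matched_pairs$gap_days[mr$matched_pairs$case_id == "TD15"],
               29L)
  # every matched pair satisfies the three criteria
  merged <- merge(merge(mr$matched_pairs, t1$index, by = "case_id"),
                  t1$reference, by = "record_id")
  expect_true(all(merged$patient_id.x == merged$patient_id.y))
  gaps <- as.integer(merged$histopath_date - merged$exam_date)
  expect_true(all(gaps >= 0 & gaps <= 548))
  expect_true(all(locations_compatible(merged$region, merged$body_site)))
})

test_that("empty reference table leaves every index test unmatched", {
  t1 <- table1_cases()
  mr <- match_records(t1$index, t1$reference[0, ])
  expect_equal(nrow(mr$matched_pairs), 0L)
  expect_equal(nrow(mr$unmatched_index), nrow(t1$index))
})

test_that("matching conserves records for both tables", {
  for (seed in 1:5) {
    g <- generate_cohort(cohort_config(n_patients = 300, prevalence = 0.03,
                                       n_ambiguous = 3L), seed = seed)
    idx <- validate_index_tests(g$index)$records
    ref <- validate_reference_tests(g$reference)$records
    mr <- match_records(idx, ref)
    led <- mr$exclusion_ledger
    n_idx_excl <- sum(led$kind == "index")
    expect_equal(nrow(mr$matched_pairs) + nrow(mr$unmatched_index) +
                   n_idx_excl, nrow(idx))
    expect_equal(nrow(mr$matched_pairs) + sum(led$kind == "reference"),
                 nrow(ref))
    expect_false(anyDuplicated(mr$matched_pairs$case_id) > 0)
    expect_false(anyDuplicated(mr$matched_pairs$record_id) > 0)
  }
})

test_that("planted links are recovered when location coding is exact", {
  # injective coarsening: one distinct site per region, so the only way to
  # lose a planted link is window censoring of a very late histopathology
  exact_sites <- stats::setNames(paste("Skin of", tolower(fine_regions())),
                                 fine_regions())
  exact_compat <- location_table(
    stats::setNames(as.list(fine_regions()), exact_sites))
  cfg <- cohort_config(n_patients = 4000, prevalence = 0.02,
                       wildcard_prob = 0, coarsening = exact_sites)
  g <- generate_cohort(cfg, seed = 11)
  idx <- validate_index_tests(g$index)$records
  ref <- validate_reference_tests(g$reference)$records
  mr <- match_records(idx, ref, compat = exact_compat)
  planted <- g$truth[!is.na(g$truth$record_id), c("case_id", "record_id")]
  hit <- merge(planted, mr$matched_pairs, by = c("case_id", "record_id"))
  expect_gte(nrow(hit) / nrow(planted), 0.99)
})
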