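# Independent oracles and small fixture builders used across the suite.

# Brute-force scenario oracle: enumerate every subset of candidate rows via
# bitmask, keep subsets that are one-to-one matchings of maximum
# cardinality, and return the attainable range of false-negative counts.
# Independent of the package's backtracking search by construction.
brute_force_fn_range <- function(candidates, labels) {
  e <- nrow(candidates)
  stopifnot(e <= 14)
  best_size <- -1L
  fns <- integer()
  for (mask in 0:(2^e - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(e) - 1)) > 0)
    if (anyDuplicated(candidates$case_id[rows]) ||
        anyDuplicated(candidates$record_id[rows])) next
    sz <- length(rows)
    if (sz > best_size) {
      best_size <- sz
      fns <- integer()
    }
    if (sz == best_size) {
      fns <- c(fns, sum(labels[candidates$case_id[rows]] == "NEGATIVE"))
    }
  }
  c(min = min(fns), max = max(fns))
}

# Random small candidate instance: a handful of index tests and references
# with random feasible edges, labels and gaps.
random_instance <- function(max_edges = 12) {
  n_idx <- sample(2:6, 1)
  n_ref <- sample(1:4, 1)
  grid <- expand.grid(i = seq_len(n_idx), r = seq_len(n_ref))
  n_e <- min(sample(seq_len(max_edges), 1), nrow(grid))
  pick <- grid[sample(nrow(grid), n_e), , drop = FALSE]
  cand <- data.frame(case_id = paste0("i", pick$i),
                     record_id = paste0("r", pick$r),
                     patient_id = "p1",
                     gap_days = sample(0:548, n_e, replace = TRUE),
                     stringsAsFactors = FALSE)
  labels <- stats::setNames(sample(c("POSITIVE", "NEGATIVE"), n_idx,
                                   replace = TRUE),
                            paste0("i", seq_len(n_idx)))
  list(candidates = cand, labels = labels)
}

# Straight-line per-case reclassification oracle for the confusion matrix:
# recount labels and match status without going through build_confusion's
# bookkeeping.
oracle_confusion <- function(match_result, index) {
  ids <- c(match_result$matched_pairs$case_id,
           match_result$unmatched_index$case_id)
  tp <- fp <- fn <- tn <- 0L
  for (cid in ids) {
    row <- index[index$case_id == cid, ]
    lab <- classify_index(row$diagnosis, row$plan, row$image_valid)
    matched <- cid %in% match_result$matched_pairs$case_id
    if (lab == "POSITIVE" && matched) tp <- tp + 1L
    if (lab == "POSITIVE" && !matched) fp <- fp + 1L
    if (lab == "NEGATIVE" && matched) fn <- fn + 1L
    if (lab == "NEGATIVE" && !matched) tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Minimal clean index/reference record builders for handmade cases.
make_index <- function(case_id, patient_id, exam_date, diagnosis, plan,
                       region, image_valid = TRUE) {
  data.frame(case_id = case_id, patient_id = patient_id,
             exam_date = as.Date(exam_date), diagnosis = diagnosis,
             plan = plan, region = region, image_valid = image_valid,
             stringsAsFactors = FALSE)
}

make_reference <- function(record_id, patient_id, histopath_date,
                           body_site, diagnosis = "C43",
                           morphology = "2092003", excision_offset = 3) {
  n <- length(record_id)
  diagnosis <- rep_len(diagnosis, n)
  morphology <- rep_len(morphology, n)
  data.frame(record_id = record_id, patient_id = patient_id,
             excision_date = as.Date(histopath_date) - excision_offset,
             histopath_date = as.Date(histopath_date),
             diagnosis = diagnosis, morphology = morphology,
             body_site = body_site, stringsAsFactors = FALSE)
}
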