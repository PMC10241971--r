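#' Enumerate index-reference match candidates
#'
#' A candidate is any index/reference pair meeting the three linkage
#' criteria: (1) the histopathology was performed within `window_days`
#' (default 548, i.e. 1.5 years) *after* the examination, boundary
#' inclusive; (2) same patient ID; (3) compatible lesion locations under
#' the coarse/fine compatibility table.  The gap is measured from the
#' examination to the histopathology date (the reference test is performed
#' at histopathology, not at excision).
#'
#' @param index clean index-test records.
#' @param reference clean reference-test records.
#' @param window_days observation window in days (inclusive).
#' @param compat a `location_table`.
#' @return data frame `case_id`, `record_id`, `patient_id`, `gap_days`,
#'   ordered by patient ID, exam date, record ID.
#' @export
find_candidates <- function(index, reference, window_days = 548L,
                            compat = load_location_table()) {
  if (nrow(index) == 0L || nrow(reference) == 0L) {
    return(data.frame(case_id = character(), record_id = character(),
                      patient_id = character(), gap_days = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- merge(index[, c("case_id", "patient_id", "exam_date", "region")],
                 reference[, c("record_id", "patient_id", "histopath_date",
                               "body_site")],
                 by = "patient_id")
  if (nrow(pairs) == 0L) {
    return(data.frame(case_id = character(), record_id = character(),
                      patient_id = character(), gap_days = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs$gap_days <- as.integer(pairs$histopath_date - pairs$exam_date)
  pairs <- pairs[pairs$gap_days >= 0L & pairs$gap_days <= window_days, ,
                 drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs <- pairs[locations_compatible(pairs$region, pairs$body_site, compat), ,
                   drop = FALSE]
  }
  pairs <- pairs[order(pairs$patient_id, pairs$exam_date, pairs$record_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs[, c("case_id", "record_id", "patient_id", "gap_days")]
}

#' Drop later index tests that concern the same lesion
#'
#' When several consecutive examinations concern the same lesion
#' (operationalized as same patient and same fine region, since the service
#' has no lesion identifier), only the earliest is kept and later ones are
#' excluded.  One exception: if the earliest carries a checkup plan and has
#' no candidate link to a positive reference test, it is itself excluded
#' (the checkup produced a follow-up examination that is the informative
#' one) and the rule re-applies to the remainder.  A lone examination is
#' always kept.
#'
#' @param index clean index-test records.
#' @param candidates candidate table from [find_candidates()].
#' @return list with `kept` (character vector of case IDs) and `exclusions`
#'   (ledger data frame).
#' @export
dedupe_consecutive <- function(index, candidates) {
  has_candidate <- index$case_id %in% candidates$case_id
  names(has_candidate) <- index$case_id
  kept <- character()
  excl_id <- character(); excl_code <- character()
  groups <- split(seq_len(nrow(index)),
                  paste(index$patient_id, index$region, sep = "\r"))
  for (g in groups) {
    g <- g[order(index$exam_date[g], index$case_id[g])]
    ids <- index$case_id[g]
    plans <- index$plan[g]
    while (length(ids) > 1L &&
           is_checkup_plan(plans[1L]) && !has_candidate[[ids[1L]]]) {
      excl_id <- c(excl_id, ids[1L])
      excl_code <- c(excl_code, "checkup_first_unmatched")
      ids <- ids[-1L]; plans <- plans[-1L]
    }
    kept <- c(kept, ids[1L])
    if (length(ids) > 1L) {
      excl_id <- c(excl_id, ids[-1L])
      excl_code <- c(excl_code, rep("later_duplicate_index", length(ids) - 1L))
    }
  }
  reasons <- c(later_duplicate_index =
                 "later examination of an already-examined lesion",
               checkup_first_unmatched =
                 "checkup-plan first examination without a positive-reference candidate")
  list(kept = kept,
       exclusions = data.frame(id = excl_id,
                               kind = rep("index", length(excl_id)),
                               stage = rep("dedupe_consecutive", length(excl_id)),
                               reason_code = excl_code,
                               reason = unname(reasons[excl_code]),
                               stringsAsFactors = FALSE))
}

#' Resolve several references competing for one index test
#'
#' When multiple positive reference tests are candidates for the same index
#' test, the pair with the least time in between is retained; ties break
#' deterministically on the smaller record ID (both choices yield the same
#' confusion matrix because tied references are interchangeable melanoma
#' records for that examination).  A dropped reference may still match a
#' different index test; if it ends up unmatched it is excluded as a
#' duplicate diagnosis.
#'
#' @param candidates candidate table from [find_candidates()].
#' @return candidate table with at most one row per `case_id`; attribute
#'   `dropped_refs` lists record IDs whose candidacy for some index test
#'   was lost here.
#' @export
resolve_duplicate_references <- function(candidates) {
  if (nrow(candidates) == 0L) {
    attr(candidates, "dropped_refs") <- character()
    return(candidates)
  }
  ord <- order(candidates$case_id, candidates$gap_days, candidates$record_id)
  cand <- candidates[ord, , drop = FALSE]
  keep <- !duplicated(cand$case_id)
  dropped <- setdiff(cand$record_id[!keep], cand$record_id[keep])
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$patient_id, out$case_id, out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_refs") <- dropped
  out
}

# Connected components of the bipartite candidate graph (index tests vs
# reference tests); ambiguity never crosses components.
candidate_components <- function(candidates) {
  nodes <- c(paste0("i\r", candidates$case_id),
             paste0("r\r", candidates$record_id))
  uniq <- unique(nodes)
  comp <- stats::setNames(seq_along(uniq), uniq)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(candidates))) {
      a <- paste0("i\r", candidates$case_id[k])
      b <- paste0("r\r", candidates$record_id[k])
      m <- min(comp[[a]], comp[[b]])
      if (comp[[a]] != m || comp[[b]] != m) {
        comp[[a]] <- m; comp[[b]] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp[paste0("i\r", candidates$case_id)]
}

# All maximum-cardinality matchings of a small candidate set, by
# backtracking over references.  Returns a list of integer row-index
# vectors into `cand`.
enumerate_matchings <- function(cand) {
  refs <- unique(cand$record_id)
  best <- list(size = -1L, sols = list())
  recurse <- function(ri, used_cases, picked) {
    if (ri > length(refs)) {
      sz <- length(picked)
      if (sz > best$size) best <<- list(size = sz, sols = list(picked))
      else if (sz == best$size) best$sols[[length(best$sols) + 1L]] <<- picked
      return(invisible(NULL))
    }
    rows <- which(cand$record_id == refs[ri] &
                    !(cand$case_id %in% used_cases))
    # upper bound prune: even matching every remaining ref can't beat best
    if (length(picked) + (length(refs) - ri + 1L) < best$size) {
      return(invisible(NULL))
    }
    recurse(ri + 1L, used_cases, picked)            # leave this ref unmatched
    for (row in rows) {
      recurse(ri + 1L, c(used_cases, cand$case_id[row]), c(picked, row))
    }
    invisible(NULL)
  }
  recurse(1L, character(), integer())
  best$sols
}

#' Resolve residual matching ambiguity under a scenario
#'
#' After the duplicate-reference rule each index test has at most one
#' candidate reference, but several index tests may still compete for one
#' reference.  Among all feasible one-to-one assignments of maximum
#' cardinality (no matchable reference is left unmatched), the worst-case
#' scenario returns one maximizing the number of false negatives under
#' `classify_fn` and the best case one minimizing it; ties break on the
#' smallest total gap in days, then on candidate order, so the result is
#' deterministic.  The search is exhaustive within each connected ambiguity
#' component; components are tiny in practice and a component with more
#' candidates than `max_component` aborts with a request for manual review.
#'
#' @param candidates candidate table (typically after
#'   [resolve_duplicate_references()]).
#' @param scenario `"WORST_CASE"` or `"BEST_CASE"`.
#' @param labels named character vector: diagnostic label per case ID (see
#'   [classify_index()]); a matched `NEGATIVE` index test is a false
#'   negative.
#' @param max_component refuse components with more candidate pairs than
#'   this (default 20).
#' @return candidate table restricted to the chosen assignment.
#' @export
resolve_scenario <- function(candidates, scenario = c("WORST_CASE", "BEST_CASE"),
                             labels, max_component = 20L) {
  scenario <- match.arg(scenario)
  if (nrow(candidates) == 0L) return(candidates)
  missing_lab <- setdiff(candidates$case_id, names(labels))
  if (length(missing_lab) > 0L) {
    stop("no diagnostic label for case(s): ",
         paste(utils::head(missing_lab, 5L), collapse = ", "))
  }
  comp <- candidate_components(candidates)
  chosen <- integer()
  for (cid in unique(comp)) {
    rows <- which(comp == cid)
    cand <- candidates[rows, , drop = FALSE]
    if (nrow(cand) > max_component) {
      stop("ambiguity component with ", nrow(cand), " candidate pairs ",
           "exceeds max_component = ", max_component,
           "; review these records manually (patient ",
           cand$patient_id[1L], ")")
    }
    sols <- enumerate_matchings(cand)
    fn <- vapply(sols, function(s) {
      sum(labels[cand$case_id[s]] == "NEGATIVE")
    }, numeric(1))
    gap <- vapply(sols, function(s) sum(cand$gap_days[s]), numeric(1))
    key <- if (scenario == "WORST_CASE") -fn else fn
    ord <- order(key, gap)
    chosen <- c(chosen, rows[sols[[ord[1L]]]])
  }
  out <- candidates[sort(chosen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match index tests to positive reference tests
#'
#' Full linkage pipeline: candidate enumeration under the three criteria,
#' same-lesion deduplication of consecutive examinations,
#' duplicate-reference resolution, scenario resolution of residual
#' ambiguity, and exclusion of reference tests left without a matched index
#' test.  Every excluded record carries a reason code in the ledger, and
#' every input record ends up in exactly one of matched / unmatched /
#' excluded.
#'
#' @param index,reference clean records (rejects removed).
#' @param scenario `"WORST_CASE"` (default, the conservative bound) or
#'   `"BEST_CASE"`.
#' @param window_days observation window (default 548 days = 1.5 years).
#' @param compat a `location_table`.
#' @param max_component see [resolve_scenario()].
#' @return object of class `match_result`: list with `matched_pairs`
#'   (`case_id`, `record_id`, `gap_days`), `unmatched_index` (data frame
#'   with `case_id`), `exclusion_ledger` (`id`, `kind`, `stage`,
#'   `reason_code`, `reason`), `scenario`, `window_days`.
#' @export
match_records <- function(index, reference,
                          scenario = c("WORST_CASE", "BEST_CASE"),
                          window_days = 548L,
                          compat = load_location_table(),
                          max_component = 20L) {
  scenario <- match.arg(scenario)
  candidates <- find_candidates(index, reference, window_days, compat)
  dd <- dedupe_consecutive(index, candidates)
  kept_index <- index[index$case_id %in% dd$kept, , drop = FALSE]
  candidates <- candidates[candidates$case_id %in% dd$kept, , drop = FALSE]
  candidates <- resolve_duplicate_references(candidates)
  dropped_refs <- attr(candidates, "dropped_refs")
  labels <- stats::setNames(
    classify_index(kept_index$diagnosis, kept_index$plan,
                   kept_index$image_valid),
    kept_index$case_id)
  assignment <- resolve_scenario(candidates, scenario, labels, max_component)

  unmatched_ref <- setdiff(reference$record_id, assignment$record_id)
  ref_code <- ifelse(unmatched_ref %in% dropped_refs,
                     "duplicate_diagnosis", "no_matched_index")
  ref_reason <- c(duplicate_diagnosis = paste(
    "second histopathology record for a lesion whose index test was",
    "already matched to an earlier similar positive reference test"),
    no_matched_index = "reference test without a matched index test")
  ledger <- rbind(dd$exclusions,
                  data.frame(id = unmatched_ref,
                             kind = rep("reference", length(unmatched_ref)),
                             stage = rep("post_matching", length(unmatched_ref)),
                             reason_code = as.character(ref_code),
                             reason = unname(ref_reason[as.character(ref_code)]),
                             stringsAsFactors = FALSE))
  unmatched_index <- setdiff(kept_index$case_id, assignment$case_id)
  structure(list(
    matched_pairs = assignment[, c("case_id", "record_id", "gap_days")],
    unmatched_index = data.frame(case_id = unmatched_index,
                                 stringsAsFactors = FALSE),
    exclusion_ledger = ledger,
    scenario = scenario,
    window_days = as.integer(window_days)), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("match result (", x$scenario, ", window ", x$window_days, " days)\n",
      sep = "")
  cat("  matched pairs:   ", nrow(x$matched_pairs), "\n")
  cat("  unmatched index: ", nrow(x$unmatched_index), "\n")
  cat("  exclusions:      ", nrow(x$exclusion_ledger), "\n")
  invisible(x)
}
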