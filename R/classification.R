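#' Classify an index test for diagnostic accuracy
#'
#' Labels every examination with exactly one of four outcomes:
#'
#' * `INVALID_INCONCLUSIVE` -- the dermatologist deemed the images unusable;
#' * `POSITIVE` -- melanoma diagnosis (C43 or D03), or a neoplasm of
#'   uncertain/unknown behaviour of skin (D48.5 or D48) together with an
#'   excision or biopsy recommendation;
#' * `VALID_INCONCLUSIVE` -- the recommendation defers the decision
#'   ("visit dermatologist" or a 1-month checkup);
#' * `NEGATIVE` -- every other diagnosis/plan combination.
#'
#' Precedence is invalid > melanoma diagnosis > D48-with-excision >
#' valid-inconclusive > negative, so a melanoma-coded examination is
#' positive whatever its plan.  Both inconclusive labels are excluded from
#' the 2x2 statistics but counted for the test yield.
#'
#' @param diagnosis character vector of normalized ICD-10 categories.
#' @param plan character vector of management-plan codes.
#' @param image_valid logical vector; `FALSE` means unusable images.
#' @return character vector of labels.
#' @examples
#' classify_index("D48.5", "EXCISION", TRUE)      # POSITIVE
#' classify_index("D48.5", "VISIT_DERMATOLOGIST", TRUE)  # VALID_INCONCLUSIVE
#' classify_index("D22", "CHECKUP_12M", TRUE)     # NEGATIVE
#' @export
classify_index <- function(diagnosis, plan, image_valid = TRUE) {
  n <- max(length(diagnosis), length(plan), length(image_valid))
  diagnosis <- rep_len(diagnosis, n)
  plan <- rep_len(plan, n)
  image_valid <- rep_len(image_valid, n)
  if (anyNA(diagnosis)) {
    stop("unmappable diagnosis among index tests; reject such rows before ",
         "classification")
  }
  bad_plan <- !(plan %in% management_plans())
  if (any(bad_plan)) {
    stop("unknown management plan(s): ", paste(unique(plan[bad_plan]),
                                               collapse = ", "))
  }
  out <- rep("NEGATIVE", n)
  out[plan %in% c("VISIT_DERMATOLOGIST", "CHECKUP_1M")] <- "VALID_INCONCLUSIVE"
  d48_pos <- diagnosis %in% c("D48", "D48.5") & plan %in% c("EXCISION", "BIOPSY")
  out[d48_pos] <- "POSITIVE"
  out[diagnosis %in% c("C43", "D03")] <- "POSITIVE"
  out[!image_valid] <- "INVALID_INCONCLUSIVE"
  out
}

#' Classify the management plan of a histopathology-confirmed melanoma
#'
#' For index tests matched to a positive reference test (melanoma confirmed
#' by histopathology), the recommended action is correct when it leads to
#' tissue diagnosis or specialist review: excision, biopsy, or a
#' dermatologist visit.  A 1-month checkup is inconclusive and drops out of
#' the denominator; every other plan (longer checkups, no action) is
#' incorrect.
#'
#' @param plan character vector of management-plan codes.
#' @return character vector with values `"CORRECT"`, `"INCORRECT"`,
#'   `"INCONCLUSIVE"`.
#' @export
classify_management <- function(plan) {
  bad <- !(plan %in% management_plans())
  if (any(bad)) {
    stop("unknown management plan(s): ", paste(unique(plan[bad]),
                                               collapse = ", "))
  }
  out <- rep("INCORRECT", length(plan))
  out[plan %in% c("EXCISION", "BIOPSY", "VISIT_DERMATOLOGIST")] <- "CORRECT"
  out[plan == "CHECKUP_1M"] <- "INCONCLUSIVE"
  out
}

#' Build the 2x2 confusion matrix from a match result
#'
#' Reference positivity is the existence of a matched melanoma
#' histopathology record; absence of one within the observation window is a
#' negative reference test.  Over conclusive index tests only: matched and
#' positive is a true positive, matched and negative a false negative,
#' unmatched and positive a false positive, unmatched and negative a true
#' negative.  Matched-but-inconclusive index tests (e.g. a confirmed
#' melanoma whose plan was a dermatologist visit) stay out of the matrix but
#' are counted, as are unmatched inconclusive tests, for the yield
#' accounting.
#'
#' @param match_result a `match_result` from [match_records()].
#' @param index clean index-test records (the matcher's input).
#' @return object of class `confusion_matrix`: list with integer `tp`,
#'   `fp`, `fn`, `tn`, `n_conclusive`, `n_valid_inconclusive`,
#'   `n_invalid_inconclusive`.
#' @export
build_confusion <- function(match_result, index) {
  stopifnot(inherits(match_result, "match_result"))
  analysis <- index[index$case_id %in% c(match_result$matched_pairs$case_id,
                                         match_result$unmatched_index$case_id), ,
                    drop = FALSE]
  if (nrow(analysis) == 0L) {
    return(new_confusion(0L, 0L, 0L, 0L, 0L, 0L))
  }
  label <- classify_index(analysis$diagnosis, analysis$plan,
                          analysis$image_valid)
  matched <- analysis$case_id %in% match_result$matched_pairs$case_id
  new_confusion(tp = sum(matched & label == "POSITIVE"),
                fp = sum(!matched & label == "POSITIVE"),
                fn = sum(matched & label == "NEGATIVE"),
                tn = sum(!matched & label == "NEGATIVE"),
                n_valid = sum(label == "VALID_INCONCLUSIVE"),
                n_invalid = sum(label == "INVALID_INCONCLUSIVE"))
}

new_confusion <- function(tp, fp, fn, tn, n_valid, n_invalid) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_conclusive = as.integer(tp + fp + fn + tn),
                 n_valid_inconclusive = as.integer(n_valid),
                 n_invalid_inconclusive = as.integer(n_invalid)),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from bare counts
#'
#' Convenience constructor for the 2x2-only workflow (reproducing interval
#' estimates from published cross-tabulations without any linkage step).
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @param n_valid,n_invalid inconclusive counts (default 0).
#' @return a `confusion_matrix`.
#' @examples
#' confusion_matrix(tp = 19, fp = 351, fn = 2, tn = 4376)
#' @export
confusion_matrix <- function(tp, fp, fn, tn, n_valid = 0L, n_invalid = 0L) {
  new_confusion(tp, fp, fn, tn, n_valid, n_invalid)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("2x2 confusion matrix (index test vs histopathology reference)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(index = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  cat("conclusive:", x$n_conclusive,
      " valid inconclusive:", x$n_valid_inconclusive,
      " invalid inconclusive:", x$n_invalid_inconclusive, "\n")
  invisible(x)
}
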