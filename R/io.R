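#' @keywords internal
parse_iso_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

# Reject reasons name the matching criterion they break so the exclusion
# ledger maps directly onto the flow accounting: (1) time window, (2) patient
# identity, (3) lesion location.
reject_reason <- function(code) {
  c(missing_date = "missing matching criterion (1): unparseable or absent date",
    missing_patient = "missing matching criterion (2): absent patient ID",
    missing_location = "missing matching criterion (3): unknown or absent lesion location",
    unknown_diagnosis = "unmappable ICD-10 diagnosis code",
    unknown_plan = "unknown management-plan code",
    date_order = "histopathology date precedes excision date")[code]
}

validate_common <- function(raw, path, key_col, kind) {
  if (anyDuplicated(raw[[key_col]])) {
    dup <- unique(raw[[key_col]][duplicated(raw[[key_col]])])
    stop("duplicated ", key_col, " in ", kind, " table: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  invisible(NULL)
}

new_rejects <- function(id = character(), reason_code = character()) {
  data.frame(id = as.character(id), reason_code = as.character(reason_code),
             reason = unname(reject_reason(as.character(reason_code))),
             stringsAsFactors = FALSE)
}

#' Validate raw index-test rows
#'
#' Splits a raw index-test table into clean records and a rejects ledger.
#' A row is rejected (never imputed) when any matching criterion cannot be
#' evaluated: missing patient ID, unparseable exam date, unknown lesion
#' region -- or when its diagnosis or plan code falls outside the controlled
#' vocabularies.  Rows with `image_valid = FALSE` are *kept*: they are
#' classified invalid-inconclusive downstream, not rejected.
#'
#' @param raw data frame with columns `case_id`, `patient_id`, `exam_date`,
#'   `diagnosis`, `plan`, `region`, `image_valid`.
#' @return list with `records` (clean, typed data frame, original order) and
#'   `rejects` (data frame `id`, `reason_code`, `reason`).
#' @export
validate_index_tests <- function(raw) {
  need <- c("case_id", "patient_id", "exam_date", "diagnosis", "plan",
            "region", "image_valid")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("index-test table is missing column(s): ", paste(miss, collapse = ", "))
  }
  validate_common(raw, key_col = "case_id", kind = "index-test")
  pid <- trimws(as.character(raw$patient_id))
  date <- parse_iso_date(raw$exam_date)
  region <- trimws(as.character(raw$region))
  diag <- normalize_icd(as.character(raw$diagnosis))
  plan <- trimws(toupper(as.character(raw$plan)))
  valid <- as.logical(raw$image_valid)

  reason <- rep(NA_character_, nrow(raw))
  put <- function(reason_vec, cond, code) ifelse(is.na(reason_vec) & cond, code, reason_vec)
  reason <- put(reason, is.na(pid) | !nzchar(pid), "missing_patient")
  reason <- put(reason, is.na(date), "missing_date")
  reason <- put(reason, !(region %in% fine_regions()), "missing_location")
  reason <- put(reason, is.na(diag), "unknown_diagnosis")
  reason <- put(reason, !(plan %in% management_plans()), "unknown_plan")

  keep <- is.na(reason)
  records <- data.frame(case_id = as.character(raw$case_id)[keep],
                        patient_id = pid[keep], exam_date = date[keep],
                        diagnosis = diag[keep], plan = plan[keep],
                        region = region[keep],
                        image_valid = ifelse(is.na(valid[keep]), TRUE, valid[keep]),
                        stringsAsFactors = FALSE)
  list(records = records,
       rejects = new_rejects(as.character(raw$case_id)[!keep], reason[!keep]))
}

#' Validate raw reference-test rows
#'
#' Same contract as [validate_index_tests()] for the histopathology extract:
#' rows missing patient ID, dates or body site are rejected, as are rows
#' whose histopathology date precedes the excision date.  Morphology is kept
#' verbatim (any digit string is permitted; unknown concepts classify as
#' non-melanoma via [morphology_to_icd()]).
#'
#' @param raw data frame with columns `record_id`, `patient_id`,
#'   `excision_date`, `histopath_date`, `diagnosis`, `morphology`,
#'   `body_site`.
#' @return list with `records` and `rejects` as in [validate_index_tests()].
#' @export
validate_reference_tests <- function(raw) {
  need <- c("record_id", "patient_id", "excision_date", "histopath_date",
            "diagnosis", "morphology", "body_site")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("reference-test table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  validate_common(raw, key_col = "record_id", kind = "reference-test")
  pid <- trimws(as.character(raw$patient_id))
  exc <- parse_iso_date(raw$excision_date)
  his <- parse_iso_date(raw$histopath_date)
  site <- trimws(as.character(raw$body_site))
  diag <- normalize_icd(as.character(raw$diagnosis))

  reason <- rep(NA_character_, nrow(raw))
  put <- function(reason_vec, cond, code) ifelse(is.na(reason_vec) & cond, code, reason_vec)
  reason <- put(reason, is.na(pid) | !nzchar(pid), "missing_patient")
  reason <- put(reason, is.na(exc) | is.na(his), "missing_date")
  reason <- put(reason, !is.na(exc) & !is.na(his) & his < exc, "date_order")
  reason <- put(reason, !nzchar(site), "missing_location")
  reason <- put(reason, is.na(diag), "unknown_diagnosis")

  keep <- is.na(reason)
  records <- data.frame(record_id = as.character(raw$record_id)[keep],
                        patient_id = pid[keep], excision_date = exc[keep],
                        histopath_date = his[keep], diagnosis = diag[keep],
                        morphology = trimws(as.character(raw$morphology))[keep],
                        body_site = site[keep], stringsAsFactors = FALSE)
  list(records = records,
       rejects = new_rejects(as.character(raw$record_id)[!keep], reason[!keep]))
}

#' Read and write the two input tables
#'
#' Delimited-text (CSV) readers and writers for the service (index-test) and
#' histopathology (reference-test) tables.  Reading validates every row;
#' clean rows come back typed (dates as `Date`) in file order, flawed rows
#' land in a rejects ledger with a criterion-specific reason.  A missing
#' required column or duplicated key is a hard error.  Writing then reading
#' a clean table is the identity on all fields.
#'
#' @param path file path.
#' @param records clean records as returned in `$records`.
#' @return readers return `list(records, rejects)`; writers return `path`
#'   invisibly.
#' @export
read_index_tests <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_index_tests(raw)
}

#' @rdname read_index_tests
#' @export
read_reference_tests <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_reference_tests(raw)
}

#' @rdname read_index_tests
#' @export
write_index_tests <- function(records, path) {
  out <- records
  out$exam_date <- format(out$exam_date, "%Y-%m-%d")
  out$image_valid <- ifelse(out$image_valid, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname read_index_tests
#' @export
write_reference_tests <- function(records, path) {
  out <- records
  out$excision_date <- format(out$excision_date, "%Y-%m-%d")
  out$histopath_date <- format(out$histopath_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
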