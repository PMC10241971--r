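as_input_table <- function(x, reader, validator) {
  if (is.character(x) && length(x) == 1L) return(reader(x))
  validator(x)
}

#' Run the full evaluation pipeline
#'
#' Validation, three-criterion matching with scenario resolution,
#' classification, and interval estimation in one deterministic call:
#' same inputs, scenario and window give identical output.  Degenerate
#' inputs do not crash: with no matched melanoma (`n1 = 0`) the
#' sensitivity, predictive values and management accuracy are reported as
#' `NA`.
#'
#' @param index index-test table: a path to a delimited file or a raw data
#'   frame.
#' @param reference reference-test table, likewise.
#' @param scenario `"WORST_CASE"` (default) or `"BEST_CASE"`.
#' @param window_days observation window in days (default 548).
#' @param level confidence level (default 0.95).
#' @param compat a `location_table`.
#' @param max_component see [resolve_scenario()].
#' @return object of class `pipeline_result`: list with `report` (point
#'   estimates and intervals plus `test_yield`), `flow` (`flow_counts`),
#'   `confusion` (`confusion_matrix`), `cases` (per-case audit table),
#'   `exclusions` (full ledger), `match` (`match_result`), `scenario`,
#'   `level`.
#' @export
run_pipeline <- function(index, reference,
                         scenario = c("WORST_CASE", "BEST_CASE"),
                         window_days = 548L, level = 0.95,
                         compat = load_location_table(),
                         max_component = 20L) {
  scenario <- match.arg(scenario)
  idx <- as_input_table(index, read_index_tests, validate_index_tests)
  ref <- as_input_table(reference, read_reference_tests,
                        validate_reference_tests)
  n_loaded_index <- nrow(idx$records) + nrow(idx$rejects)
  n_loaded_ref <- nrow(ref$records) + nrow(ref$rejects)

  mr <- match_records(idx$records, ref$records, scenario = scenario,
                      window_days = window_days, compat = compat,
                      max_component = max_component)
  cm <- build_confusion(mr, idx$records)

  analysis_ids <- c(mr$matched_pairs$case_id, mr$unmatched_index$case_id)
  cases <- idx$records[idx$records$case_id %in% analysis_ids, , drop = FALSE]
  cases$diagnostic_label <- classify_index(cases$diagnosis, cases$plan,
                                           cases$image_valid)
  m <- match(cases$case_id, mr$matched_pairs$case_id)
  cases$matched <- !is.na(m)
  cases$record_id <- mr$matched_pairs$record_id[m]
  cases$gap_days <- mr$matched_pairs$gap_days[m]
  cases$management_label <- ifelse(cases$matched,
                                   classify_management(cases$plan),
                                   NA_character_)
  rownames(cases) <- NULL

  mgmt_labels <- cases$management_label[cases$matched]
  mgmt <- if (sum(mgmt_labels != "INCONCLUSIVE") > 0L) {
    management_accuracy(mgmt_labels, level)
  } else NULL
  acc <- if (cm$tp + cm$fn >= 1L && cm$fp + cm$tn >= 1L) {
    accuracy_measures(cm, level)
  } else NULL

  exclusions <- rbind(
    if (nrow(idx$rejects) > 0L)
      data.frame(id = idx$rejects$id, kind = "index", stage = "validation",
                 reason_code = idx$rejects$reason_code,
                 reason = idx$rejects$reason, stringsAsFactors = FALSE),
    if (nrow(ref$rejects) > 0L)
      data.frame(id = ref$rejects$id, kind = "reference", stage = "validation",
                 reason_code = ref$rejects$reason_code,
                 reason = ref$rejects$reason, stringsAsFactors = FALSE),
    mr$exclusion_ledger)
  if (is.null(exclusions)) exclusions <- mr$exclusion_ledger

  flow <- flow_counts(n_loaded_index = n_loaded_index,
                      n_loaded_reference = n_loaded_ref,
                      index_rejects = nrow(idx$rejects),
                      reference_rejects = nrow(ref$rejects),
                      ledger = exclusions, cm = cm,
                      n_matched = nrow(mr$matched_pairs),
                      n_mgmt = if (is.null(mgmt)) 0L else mgmt$n)
  yield <- if (n_loaded_index - nrow(idx$rejects) -
               cm$n_invalid_inconclusive > 0L) {
    test_yield(n_total = n_loaded_index,
               n_invalid = nrow(idx$rejects),
               n_invalid_inconclusive = cm$n_invalid_inconclusive,
               n_analyzed = cm$n_conclusive)
  } else NA_real_

  report <- list(
    scenario = scenario, level = level, window_days = as.integer(window_days),
    n_analyzed = cm$n_conclusive,
    confusion = list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
    management_accuracy = prop_as_list(mgmt),
    sensitivity = prop_as_list(if (!is.null(acc)) acc$sensitivity),
    specificity = prop_as_list(if (!is.null(acc)) acc$specificity),
    ppv = prop_as_list(if (!is.null(acc)) acc$ppv),
    npv = prop_as_list(if (!is.null(acc)) acc$npv),
    prevalence = prop_as_list(if (!is.null(acc)) acc$prevalence),
    n1 = cm$tp + cm$fn, n0 = cm$fp + cm$tn,
    test_yield = yield,
    defaults = list(window_days = as.integer(window_days),
                    scenario = scenario, level = level,
                    max_component = as.integer(max_component)))
  structure(list(report = report, flow = flow, confusion = cm, cases = cases,
                 exclusions = exclusions, match = mr, scenario = scenario,
                 level = level),
            class = "pipeline_result")
}

prop_as_list <- function(p) {
  if (is.null(p)) {
    return(list(estimate = NA_real_, conf.low = NA_real_,
                conf.high = NA_real_, x = NA_integer_, n = NA_integer_))
  }
  list(estimate = p$estimate, conf.low = p$conf.low, conf.high = p$conf.high,
       x = p$x, n = p$n)
}

#' STARD-style participant-flow counts
#'
#' Hierarchical accounting of every record through the pipeline stages:
#' loaded, rejected at validation (by reason), excluded during or after
#' matching (by reason), inconclusive, and analyzed.  Conservation holds by
#' construction: index rows loaded = rejects + matching exclusions +
#' inconclusive + analyzed, and reference rows loaded = rejects + matched +
#' post-matching exclusions.
#'
#' @param n_loaded_index,n_loaded_reference rows loaded per table.
#' @param index_rejects,reference_rejects validation reject counts.
#' @param ledger full exclusion ledger.
#' @param cm a `confusion_matrix`.
#' @param n_matched matched pairs.
#' @param n_mgmt management-accuracy denominator.
#' @return object of class `flow_counts` (nested list).
#' @export
flow_counts <- function(n_loaded_index, n_loaded_reference, index_rejects,
                        reference_rejects, ledger, cm, n_matched, n_mgmt) {
  by_reason <- function(kind, stage) {
    sub <- ledger[ledger$kind == kind & ledger$stage == stage, , drop = FALSE]
    as.list(table(sub$reason_code))
  }
  structure(list(
    index = list(
      loaded = as.integer(n_loaded_index),
      rejected = list(total = as.integer(index_rejects),
                      reasons = by_reason("index", "validation")),
      excluded_matching = by_reason("index", "dedupe_consecutive"),
      valid_inconclusive = cm$n_valid_inconclusive,
      invalid_inconclusive = cm$n_invalid_inconclusive,
      analyzed = cm$n_conclusive,
      confusion = list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)),
    reference = list(
      loaded = as.integer(n_loaded_reference),
      rejected = list(total = as.integer(reference_rejects),
                      reasons = by_reason("reference", "validation")),
      matched = as.integer(n_matched),
      excluded_post_matching = by_reason("reference", "post_matching")),
    management_denominator = as.integer(n_mgmt)),
    class = "flow_counts")
}

#' Serialize the flow accounting
#'
#' @param flow a `flow_counts`.
#' @param path optional file to write the JSON to.
#' @return JSON string (invisibly when written to `path`).
#' @export
emit_stard_flow <- function(flow, path = NULL) {
  stopifnot(inherits(flow, "flow_counts"))
  json <- jsonlite::toJSON(unclass(flow), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Write all pipeline artifacts to a directory
#'
#' Emits `report.json`, `flow.json`, `cases.tsv` (per-case audit table with
#' both labels and match status) and `exclusions.tsv` (reason-coded
#' ledger).  Output is byte-identical across runs on the same input.
#'
#' @param result a `pipeline_result`.
#' @param out_dir directory (created if needed).
#' @param include_cases write the full per-case audit table (default
#'   `TRUE`); it is the largest artifact and fully regenerable, so batch
#'   drivers may skip it.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir, include_cases = TRUE) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(result$report, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "report.json"))
  emit_stard_flow(result$flow, file.path(out_dir, "flow.json"))
  if (include_cases) {
    cases <- result$cases
    cases$exam_date <- format(cases$exam_date, "%Y-%m-%d")
    utils::write.table(cases, file.path(out_dir, "cases.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "")
  }
  utils::write.table(result$exclusions, file.path(out_dir, "exclusions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("teledermatoscopy evaluation (", r$scenario, ")\n", sep = "")
  cat("  analyzed cases: ", r$n_analyzed, "  (tp ", r$confusion$tp,
      ", fp ", r$confusion$fp, ", fn ", r$confusion$fn, ", tn ",
      r$confusion$tn, ")\n", sep = "")
  pct <- function(p, d = 2) {
    if (is.na(p$estimate)) return("NA")
    sprintf("%.*f%% (%.*f-%.*f)", d, 100 * p$estimate, d, 100 * p$conf.low,
            d, 100 * p$conf.high)
  }
  cat("  management accuracy:", pct(r$management_accuracy, 1), "\n")
  cat("  sensitivity:        ", pct(r$sensitivity), "\n")
  cat("  specificity:        ", pct(r$specificity), "\n")
  cat("  PPV:                ", pct(r$ppv), "\n")
  cat("  NPV:                ", pct(r$npv), "\n")
  cat("  prevalence:         ", pct(r$prevalence), "\n")
  cat(sprintf("  test yield:          %.1f%%\n", 100 * r$test_yield))
  invisible(x)
}
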