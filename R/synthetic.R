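#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the evaluated service: roughly 1.4 examinations per
#' patient, a confirmed-melanoma prevalence of 0.44%, a dermatologist
#' reader with sensitivity 0.90 and specificity 0.93 on conclusive cases,
#' about 8% decision-deferring (valid-inconclusive) and 1.7%
#' unusable-image examinations, melanoma mostly coded as an uncertain
#' neoplasm with an excision plan rather than C43/D03 outright, lognormal
#' excision delays (median about 20 days with a long tail) plus a
#' histopathology reporting lag, and coarse SNOMED-style body-site coding
#' of reference-test locations with an occasional uninformative
#' "Skin tissue" wildcard.
#'
#' @param n_patients number of patients.
#' @param cases_geom_p geometric parameter for extra cases per patient
#'   (cases = 1 + Geom(p); default 0.72 gives about 1.4 cases/patient).
#' @param prevalence per-case probability of latent melanoma.
#' @param se_true,sp_true reader sensitivity/specificity on conclusive
#'   examinations.
#' @param p_valid_inconclusive,p_invalid probabilities of a
#'   decision-deferring plan and of unusable images (applied before the
#'   positive/negative draw, independent of disease status).
#' @param d48_convention_prob probability that a detected melanoma is coded
#'   D48.5 + excision rather than C43/D03.
#' @param insitu_prob fraction of melanomas that are in situ (D03).
#' @param excision_meanlog,excision_sdlog lognormal parameters (days) for
#'   the examination-to-excision delay.
#' @param lag_meanlog,lag_sdlog lognormal parameters (days) for the
#'   excision-to-histopathology lag.
#' @param wildcard_prob probability a reference location is coded with the
#'   wildcard site instead of the region-specific coarse site.
#' @param coarsening optional named character vector mapping each fine
#'   region to the body-site text emitted for reference records; `NULL`
#'   (default) uses the built-in coarse SNOMED-style sites, which -- like
#'   the real registry -- do not distinguish sibling regions.  Supplying an
#'   injective map emulates exact location coding.
#' @param window_days observation window.
#' @param period study period (two dates) over which examinations fall.
#' @param n_ambiguous number of planted same-patient ambiguity
#'   constellations (an extra compatible examination competing for a
#'   melanoma reference record), to exercise worst/best-case divergence.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 3400L,
                          cases_geom_p = 0.72,
                          prevalence = 0.0044,
                          se_true = 0.90,
                          sp_true = 0.93,
                          p_valid_inconclusive = 0.079,
                          p_invalid = 0.017,
                          d48_convention_prob = 0.75,
                          insitu_prob = 0.27,
                          excision_meanlog = log(20), excision_sdlog = 1.1,
                          lag_meanlog = log(15), lag_sdlog = 0.7,
                          wildcard_prob = 0.02,
                          coarsening = NULL,
                          window_days = 548L,
                          period = as.Date(c("2017-10-16", "2019-08-30")),
                          n_ambiguous = 0L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cases_geom_p = cases_geom_p, prevalence = prevalence,
              se_true = se_true, sp_true = sp_true,
              p_valid_inconclusive = p_valid_inconclusive,
              p_invalid = p_invalid,
              d48_convention_prob = d48_convention_prob,
              insitu_prob = insitu_prob,
              excision_meanlog = excision_meanlog,
              excision_sdlog = excision_sdlog,
              lag_meanlog = lag_meanlog, lag_sdlog = lag_sdlog,
              wildcard_prob = wildcard_prob,
              coarsening = coarsening,
              window_days = as.integer(window_days),
              period = as.Date(period), n_ambiguous = as.integer(n_ambiguous))
  probs <- c("cases_geom_p", "prevalence", "se_true", "sp_true",
             "p_valid_inconclusive", "p_invalid", "d48_convention_prob",
             "insitu_prob", "wildcard_prob")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("invalid config field '", nm, "': must be a probability in [0, 1]")
    }
  }
  if (cfg$n_patients < 1L) stop("invalid config field 'n_patients'")
  if (cfg$p_valid_inconclusive + cfg$p_invalid >= 1) {
    stop("invalid config fields 'p_valid_inconclusive' + 'p_invalid': sum >= 1")
  }
  if (cfg$window_days < 1L) stop("invalid config field 'window_days'")
  if (!is.null(cfg$coarsening)) {
    if (!is.character(cfg$coarsening) ||
        !all(fine_regions() %in% names(cfg$coarsening))) {
      stop("invalid config field 'coarsening': must be a character vector ",
           "named by every fine region")
    }
  }
  if (cfg$n_ambiguous < 0L) stop("invalid config field 'n_ambiguous'")
  if (length(cfg$period) != 2L || anyNA(cfg$period) ||
      cfg$period[2] <= cfg$period[1]) {
    stop("invalid config field 'period'")
  }
  structure(cfg, class = "cohort_config")
}

# Default coarse coding of a fine region, mirroring the low precision of
# SNOMED body-site texts in histopathology records.
coarsen_region <- function(region) {
  map <- c(TORSO_FRONT = "Entire skin of abdomen",
           TORSO_BACK = "Entire skin of back",
           TORSO_SIDES = "Entire skin of back",
           HEAD_NECK_FRONT = "Entire skin of cheek",
           HEAD_NECK_BACK = "Entire skin of head",
           LEFT_ARM_FRONT = "Entire skin of forearm",
           LEFT_ARM_BACK = "Entire skin of forearm",
           LEFT_ARM_UP = "Entire skin of upper arm",
           RIGHT_ARM_FRONT = "Entire skin of forearm",
           RIGHT_ARM_BACK = "Entire skin of forearm",
           RIGHT_ARM_LEFT_SIDE = "Entire skin of shoulder",
           LEFT_LEG_FRONT = "Entire skin of lower leg",
           LEFT_LEG_BACK = "Entire skin of lower leg",
           RIGHT_LEG_FRONT = "Entire skin of foot",
           RIGHT_LEG_BACK = "Entire skin of lower leg")
  unname(map[region])
}

#' Generate a synthetic service/registry cohort with ground truth
#'
#' Emits an index-test table (the service database) and a reference-test
#' table (the histopathology extract) under the model described in
#' [cohort_config()], together with the latent truth per case.  Every
#' latent melanoma case receives exactly one positive reference record --
#' reference positivity is definitional -- at a coarsened location and
#' delayed dates; whether the *index* test detects it is governed by the
#' reader model.  Non-melanoma cases never generate a reference record.
#' With a fixed seed the output is reproducible byte for byte.
#'
#' @param config a `cohort_config`.
#' @param seed integer seed; the surrounding RNG state is left untouched.
#' @return list with `index` (raw table, passes validation with zero
#'   rejects), `reference`, and `truth` (per-case data frame: `case_id`,
#'   `patient_id`, `melanoma`, `intended_label`, `record_id`).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_rng(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_cases_per <- 1L + stats::rgeom(cfg$n_patients, cfg$cases_geom_p)
  n_cases_per <- pmin(n_cases_per, length(fine_regions()))
  n <- sum(n_cases_per)
  patient <- rep(sprintf("SP%06d", seq_len(cfg$n_patients)), n_cases_per)
  region <- unlist(lapply(n_cases_per, function(k) {
    sample(fine_regions(), k, replace = FALSE)
  }), use.names = FALSE)
  exam <- cfg$period[1] +
    sample.int(as.integer(cfg$period[2] - cfg$period[1]) + 1L, n,
               replace = TRUE) - 1L
  melanoma <- stats::runif(n) < cfg$prevalence

  u <- stats::runif(n)
  state <- ifelse(u < cfg$p_invalid, "invalid",
                  ifelse(u < cfg$p_invalid + cfg$p_valid_inconclusive,
                         "valid_inconclusive", "conclusive"))
  detect <- stats::runif(n) < ifelse(melanoma, cfg$se_true, 1 - cfg$sp_true)
  # detect == TRUE means a positive-coded examination (hit for melanoma,
  # false alarm otherwise)
  diagnosis <- character(n); plan <- character(n)
  pos <- state == "conclusive" & detect
  d48 <- pos & stats::runif(n) < cfg$d48_convention_prob
  diagnosis[d48] <- sample(c("D48.5", "D48"), sum(d48), replace = TRUE,
                           prob = c(0.85, 0.15))
  plan[d48] <- sample(c("EXCISION", "BIOPSY"), sum(d48), replace = TRUE,
                      prob = c(0.9, 0.1))
  outright <- pos & !d48
  diagnosis[outright] <- ifelse(stats::runif(sum(outright)) < cfg$insitu_prob,
                                "D03", "C43")
  plan[outright] <- "EXCISION"
  neg <- state == "conclusive" & !detect
  diag_w <- fixture_diag_weights()
  diagnosis[neg] <- sample(names(diag_w), sum(neg), replace = TRUE,
                           prob = diag_w)
  plan[neg] <- sample(c("NO_ACTION", "CHECKUP_3M", "CHECKUP_6M",
                        "CHECKUP_12M", "EXCISION"), sum(neg), replace = TRUE,
                      prob = c(0.62, 0.09, 0.10, 0.12, 0.07))
  plan[neg & diagnosis %in% c("D48", "D48.5") &
         plan %in% c("EXCISION", "BIOPSY")] <- "NO_ACTION"
  vinc <- state == "valid_inconclusive"
  diagnosis[vinc] <- sample(names(diag_w), sum(vinc), replace = TRUE,
                            prob = diag_w)
  plan[vinc] <- sample(c("VISIT_DERMATOLOGIST", "CHECKUP_1M"), sum(vinc),
                       replace = TRUE, prob = c(0.6, 0.4))
  inval <- state == "invalid"
  diagnosis[inval] <- "D22"
  plan[inval] <- "NO_ACTION"

  case_id <- sprintf("SC%06d", seq_len(n))
  index <- data.frame(case_id = case_id, patient_id = patient,
                      exam_date = format(exam, "%Y-%m-%d"),
                      diagnosis = diagnosis, plan = plan, region = region,
                      image_valid = ifelse(inval, "FALSE", "TRUE"),
                      stringsAsFactors = FALSE)

  mel <- which(melanoma)
  delay <- round(stats::rlnorm(length(mel), cfg$excision_meanlog,
                               cfg$excision_sdlog))
  lag <- round(stats::rlnorm(length(mel), cfg$lag_meanlog, cfg$lag_sdlog))
  site <- if (is.null(cfg$coarsening)) coarsen_region(region[mel]) else
    unname(cfg$coarsening[region[mel]])
  site[stats::runif(length(mel)) < cfg$wildcard_prob] <- "Skin tissue"
  insitu <- stats::runif(length(mel)) < cfg$insitu_prob
  morphology <- ifelse(insitu,
                       sample(c("77986002", "61217001"), length(mel),
                              replace = TRUE, prob = c(0.8, 0.2)),
                       sample(c("55320002", "2092003", "44474009"),
                              length(mel), replace = TRUE,
                              prob = c(0.5, 0.4, 0.1)))
  reference <- data.frame(
    record_id = sprintf("SR%06d", seq_along(mel)),
    patient_id = patient[mel],
    excision_date = format(exam[mel] + delay, "%Y-%m-%d"),
    histopath_date = format(exam[mel] + delay + lag, "%Y-%m-%d"),
    diagnosis = ifelse(insitu, "D03", "C43"),
    morphology = morphology, body_site = site, stringsAsFactors = FALSE)

  truth <- data.frame(case_id = case_id, patient_id = patient,
                      melanoma = melanoma,
                      intended_label = ifelse(state != "conclusive",
                                              toupper(state),
                                              ifelse(melanoma,
                                                     ifelse(detect, "TP", "FN"),
                                                     ifelse(detect, "FP", "TN"))),
                      record_id = NA_character_, stringsAsFactors = FALSE)
  truth$record_id[mel] <- reference$record_id

  if (cfg$n_ambiguous > 0L) {
    planted <- plant_ambiguity(index, reference, truth, cfg)
    index <- planted$index; truth <- planted$truth
  }
  list(index = index, reference = reference, truth = truth)
}

# Add, for up to n_ambiguous melanoma references, a second examination of
# the same patient at a sibling region compatible with the same coarse
# site, coded oppositely to the original (positive vs negative), so the
# matcher faces a genuine worst/best-case choice.
plant_ambiguity <- function(index, reference, truth, cfg) {
  compat <- load_location_table()
  mel_cases <- truth$case_id[!is.na(truth$record_id) &
                               truth$intended_label %in% c("TP", "FN")]
  take <- utils::head(mel_cases, cfg$n_ambiguous)
  extra <- list()
  for (cid in take) {
    row <- index[index$case_id == cid, ]
    rid <- truth$record_id[truth$case_id == cid]
    ref <- reference[reference$record_id == rid, ]
    if (ref$body_site %in% compat$wildcard) {
      siblings <- fine_regions()
    } else {
      siblings <- compat$map[[ref$body_site]]
    }
    siblings <- setdiff(siblings, index$region[index$patient_id == row$patient_id])
    if (length(siblings) == 0L) next
    was_pos <- classify_index(row$diagnosis, row$plan, TRUE) == "POSITIVE"
    extra[[cid]] <- data.frame(
      case_id = paste0(cid, "B"), patient_id = row$patient_id,
      exam_date = format(as.Date(row$exam_date) + 3L, "%Y-%m-%d"),
      diagnosis = if (was_pos) "D22" else "D48.5",
      plan = if (was_pos) "NO_ACTION" else "EXCISION",
      region = siblings[1L], image_valid = "TRUE",
      stringsAsFactors = FALSE)
  }
  if (length(extra) > 0L) {
    add <- do.call(rbind, extra)
    index <- rbind(index, add)
    truth <- rbind(truth, data.frame(
      case_id = add$case_id, patient_id = add$patient_id, melanoma = FALSE,
      intended_label = "AMBIGUITY_PROBE", record_id = NA_character_,
      stringsAsFactors = FALSE))
  }
  list(index = index, truth = truth)
}
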