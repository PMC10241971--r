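#' Controlled vocabularies
#'
#' The service records a closed set of management plans and a closed set of
#' fine-grained body regions (lesion locations are picked on a body map, so
#' free text never occurs on the index-test side).  Histopathology records
#' carry a much coarser SNOMED-CT-style body-site text; compatibility between
#' the two granularities is handled by [load_location_table()].
#'
#' @return `management_plans()` and `fine_regions()` return character vectors
#'   of the valid codes.  `plan_checkup_months()` returns the checkup horizon
#'   in months for `CHECKUP_*` plans and `NA` otherwise.
#' @examples
#' management_plans()
#' plan_checkup_months(c("CHECKUP_6M", "EXCISION"))
#' @export
management_plans <- function() {
  c("EXCISION", "BIOPSY", "VISIT_DERMATOLOGIST",
    "CHECKUP_1M", "CHECKUP_3M", "CHECKUP_4M", "CHECKUP_5M", "CHECKUP_6M",
    "CHECKUP_12M", "NO_ACTION")
}

#' @rdname management_plans
#' @export
fine_regions <- function() {
  c("TORSO_FRONT", "TORSO_BACK", "TORSO_SIDES",
    "HEAD_NECK_FRONT", "HEAD_NECK_BACK",
    "LEFT_ARM_FRONT", "LEFT_ARM_BACK", "LEFT_ARM_UP",
    "RIGHT_ARM_FRONT", "RIGHT_ARM_BACK", "RIGHT_ARM_LEFT_SIDE",
    "LEFT_LEG_FRONT", "LEFT_LEG_BACK",
    "RIGHT_LEG_FRONT", "RIGHT_LEG_BACK")
}

#' @rdname management_plans
#' @param plan character vector of management-plan codes.
#' @export
plan_checkup_months <- function(plan) {
  months <- c(CHECKUP_1M = 1L, CHECKUP_3M = 3L, CHECKUP_4M = 4L,
              CHECKUP_5M = 5L, CHECKUP_6M = 6L, CHECKUP_12M = 12L)
  out <- unname(months[plan])
  out
}

#' Is a plan any of the checkup variants?
#' @param plan character vector of management-plan codes.
#' @return logical vector.
#' @export
is_checkup_plan <- function(plan) {
  !is.na(plan_checkup_months(plan))
}

# ICD-10 categories the classifier understands.  D48.5 (neoplasm of uncertain
# behaviour, skin) is kept distinct from its parent D48 because the positivity
# rule names both; every other subcode collapses to its 3-character category.
icd_known_categories <- function() {
  c("C43", "D03", "D22", "D48", "D48.5", "L82", "D18", "D23", "L81", "D21")
}

#' Normalize a raw ICD-10 code to its analysis category
#'
#' Codes are matched case-insensitively and with or without the subcode dot
#' (`"D48.5"`, `"D485"` and `"d48.5"` are all the same category).  Subcodes
#' collapse to their 3-character parent category, except the skin subcode
#' D48.5 which stays distinct because the index-test positivity rule treats
#' D48.5 and D48 separately.  A code outside the known category list maps to
#' `NA`, the explicit unmappable marker -- callers must decide whether that
#' is a reject or an error, it is never passed through silently.
#'
#' @param code character vector of raw ICD-10 codes.
#' @return character vector of categories (`NA` where unmappable).
#' @examples
#' normalize_icd(c("C43.5", "d03", "D485", "D48.9", "X99"))
#' @export
normalize_icd <- function(code) {
  stopifnot(is.character(code) | is.factor(code))
  code <- toupper(trimws(as.character(code)))
  out <- rep(NA_character_, length(code))
  nonempty <- !is.na(code) & nzchar(code)
  compact <- gsub(".", "", code, fixed = TRUE)
  # D48.5 first: it must not collapse into D48
  d485 <- nonempty & compact == "D485"
  out[d485] <- "D48.5"
  parents <- setdiff(icd_known_categories(), "D48.5")
  cat3 <- substr(compact, 1L, 3L)
  hit <- nonempty & !d485 & cat3 %in% parents &
    grepl("^[A-Z][0-9]{2}[0-9]*$", compact)
  out[hit] <- cat3[hit]
  out
}

#' Map a SNOMED-CT-style morphology identifier to an ICD-10 melanoma category
#'
#' Static map covering the morphology concepts seen in melanoma
#' histopathology records: superficial spreading melanoma (55320002),
#' malignant melanoma NOS (2092003) and malignant melanoma in Hutchinson
#' melanotic freckle (44474009) map to invasive melanoma C43; melanoma in
#' situ (77986002) and Hutchinson melanotic freckle (61217001) map to
#' melanoma in situ D03.  Every other identifier maps to `"OTHER"`; the map
#' is a total function and never errors.
#'
#' @param morphology character (or numeric) vector of concept identifiers.
#' @return character vector with values `"C43"`, `"D03"` or `"OTHER"`.
#' @examples
#' morphology_to_icd(c("55320002", "77986002", "99999999"))
#' @export
morphology_to_icd <- function(morphology) {
  map <- c("55320002" = "C43", "2092003" = "C43", "44474009" = "C43",
           "61217001" = "D03", "77986002" = "D03")
  key <- trimws(as.character(morphology))
  out <- unname(map[key])
  out[is.na(out)] <- "OTHER"
  out
}

#' Load a location-compatibility table
#'
#' Histopathology body sites are coarse ("Entire skin of back") while the
#' service records one of 15 fine body-map regions; the matcher's location
#' criterion accepts a pair when the fine region belongs to the coarse
#' site's compatible set.  The table ships as an editable delimited text
#' file (columns `body_site`, `regions` semicolon-separated, `wildcard`)
#' so users can extend the site vocabulary; the packaged default covers the
#' sites occurring in the study data, with "Skin tissue" as the wildcard
#' site compatible with every region.
#'
#' @param path path to the table; default is the packaged file.
#' @return object of class `location_table`: list with `map` (named list of
#'   region sets) and `wildcard` (character vector of wildcard site names).
#' @export
load_location_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "location_compatibility.csv",
                        package = "teledermacc", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("body_site", "regions", "wildcard")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("location table is missing column(s): ", paste(miss, collapse = ", "))
  }
  map <- lapply(strsplit(tab$regions, ";", fixed = TRUE), trimws)
  names(map) <- tab$body_site
  location_table(map, tab$body_site[as.logical(tab$wildcard)])
}

#' Construct a location-compatibility table programmatically
#'
#' @param map named list: coarse body-site text to character vector of
#'   compatible fine regions.
#' @param wildcard character vector of site names compatible with every
#'   region.
#' @return a `location_table`.
#' @export
location_table <- function(map, wildcard = character()) {
  stopifnot(is.list(map), !is.null(names(map)) || length(map) == 0L)
  bad <- setdiff(unlist(map), c(fine_regions(), ""))
  if (length(bad) > 0L) {
    stop("unknown region(s) in location map: ", paste(bad, collapse = ", "))
  }
  structure(list(map = map, wildcard = as.character(wildcard)),
            class = "location_table")
}

#' Are a fine region and a coarse body site compatible?
#'
#' @param region character vector of fine regions (see [fine_regions()]).
#' @param site character vector of coarse body-site texts (recycled).
#' @param table a `location_table`, default the packaged one.
#' @return logical vector; `TRUE` where the site's compatible set contains
#'   the region or the site is the wildcard.
#' @examples
#' locations_compatible("TORSO_FRONT", "Entire skin of abdomen")
#' locations_compatible("TORSO_BACK", "Skin tissue")
#' @export
locations_compatible <- function(region, site, table = load_location_table()) {
  stopifnot(inherits(table, "location_table"))
  n <- max(length(region), length(site))
  region <- rep_len(region, n)
  site <- rep_len(site, n)
  unknown <- !(site %in% c(names(table$map), table$wildcard))
  if (any(unknown)) {
    stop("unmappable body site(s): ",
         paste(unique(site[unknown]), collapse = "; "))
  }
  mapply(function(r, s) {
    if (s %in% table$wildcard) return(TRUE)
    r %in% table$map[[s]]
  }, region, site, USE.NAMES = FALSE)
}
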