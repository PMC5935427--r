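# Classification tables: ICD-10 chapters, GBD broad cause groups, age bins.
#
# Disease spending is reported at the level of ICD-10 chapters (letter-ranged
# code blocks) and, more coarsely, the three Global Burden of Disease broad
# cause groups: Group I (communicable, maternal, perinatal and nutritional),
# Group II (non-communicable) and Group III (injuries).

#' Controlled vocabularies used throughout the accounts
#'
#' Character vectors enumerating the closed categories of the accounting
#' domain: provider types, encounter service types, payer categories on a
#' patient bill, health-care functions of the accounts cube, and financing
#' schemes.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
che_provider_types <- c(
  "provincial_hospital", "general_hospital", "specialized_hospital",
  "tcm_hospital", "maternal_child_center", "outpatient_service_institution",
  "township_hospital", "community_health_center",
  "village_or_individual_clinic", "public_health_institution"
)

#' @rdname vocabularies
#' @export
che_service_types <- c(
  "outpatient_curative", "outpatient_preventive", "inpatient", "public_health"
)

#' @rdname vocabularies
#' @export
che_payer_categories <- c(
  "social_insurance", "commercial_insurance", "donation",
  "government_program", "out_of_pocket"
)

#' @rdname vocabularies
#' @export
che_functions <- c(
  "curative_outpatient", "curative_inpatient", "prevention",
  "assistant_services", "medicine", "management"
)

#' @rdname vocabularies
#' @export
che_financing_schemes <- c("government", "social", "household")

# payer category -> financing scheme
payer_scheme_map <- c(
  social_insurance = "social",
  commercial_insurance = "social",
  donation = "social",
  government_program = "government",
  out_of_pocket = "household"
)

icd_chapter_table <- function() {
  tibble::tribble(
    ~start, ~end, ~chapter,
    "A00", "B99", "Infectious diseases and parasitic diseases",
    "C00", "D48", "Tumor",
    "D50", "D89", "Blood diseases",
    "E00", "E90", "Endocrine, nutritional and metabolic disease",
    "F00", "F99", "Mental and behavior disorders",
    "G00", "G99", "Nervous system diseases",
    "H00", "H59", "Eye diseases",
    "H60", "H95", "Ear diseases",
    "I00", "I99", "Circulatory system diseases",
    "J00", "J99", "Respiratory system diseases",
    "K00", "K93", "Digestive system diseases",
    "L00", "L99", "Skin and subcutaneous tissue disease",
    "M00", "M99", "Muscular and connective tissue diseases",
    "N00", "N99", "Urogenital system diseases",
    "O00", "O99", "Pregnancy, childbirth and puerperium diseases",
    "P00", "P96", "Perinatal diseases",
    "Q00", "Q99", "Congenital anomalies and chromosomal abnormalities",
    "R00", "R94", "Symptoms, signs, clinical and laboratory abnormalities",
    "R95", "R99", "Death",
    "S00", "T98", "Injury, poisoning and external causes",
    "V01", "Y98", "Injury, poisoning and external causes",
    "Z00", "Z99", "Factors influencing health status"
  )
}

default_gbd_map <- function(chapters) {
  group_i <- c(
    "Infectious diseases and parasitic diseases",
    "Pregnancy, childbirth and puerperium diseases",
    "Perinatal diseases"
  )
  group_iii <- "Injury, poisoning and external causes"
  out <- setNames(rep("group_II_noncommunicable", length(chapters)), chapters)
  out[chapters %in% group_i] <- "group_I_communicable_maternal_perinatal_nutritional"
  out[chapters %in% group_iii] <- "group_III_injury"
  out
}

#' Default classification rules
#'
#' Builds the rule set that maps ICD-10 codes to the 21 chapter labels used in
#' the disease tables (with "Death" split out of the symptoms chapter as codes
#' R95--R99, the ill-defined causes of mortality), chapters to the three GBD
#' broad cause groups, and integer ages to bins. Age bins default to
#' single-year bins `"0-1"` ... `"13-14"` over half-open intervals
#' `[lower, upper)`, plus an explicit `"14"` overflow bin so that the child
#' scope (age 14 inclusive) is fully covered; the overflow bin is flagged and
#' excluded from single-year report columns but included in child totals.
#'
#' The GBD mapping is chapter-coarse: every code in a chapter inherits the
#' chapter's group, so e.g. respiratory infections fall under Group II via the
#' respiratory chapter. Supply your own `gbd_group_map` for a finer mapping.
#'
#' @return A list of class `classification_rules` with elements
#'   `icd_chapter_ranges` (tibble: start, end, chapter), `gbd_group_map`
#'   (named character), `age_bins` (tibble: lower, upper, label, overflow) and
#'   a precomputed `chapter_lookup` over all three-character code prefixes.
#' @export
default_classification_rules <- function() {
  ranges <- icd_chapter_table()
  bins <- tibble::tibble(
    lower = 0:14,
    upper = 1:15,
    label = c(paste0(0:13, "-", 1:14), "14"),
    overflow = c(rep(FALSE, 14), TRUE)
  )
  rules <- list(
    icd_chapter_ranges = ranges,
    gbd_group_map = default_gbd_map(unique(ranges$chapter)),
    age_bins = bins
  )
  rules$chapter_lookup <- build_chapter_lookup(ranges)
  structure(rules, class = "classification_rules")
}

# Expand letter-ranged chapter blocks to a named lookup over all 2600
# three-character prefixes A00..Z99; prefixes not covered map to "unclassified".
build_chapter_lookup <- function(ranges) {
  all_codes <- paste0(rep(LETTERS, each = 100), sprintf("%02d", 0:99))
  lookup <- setNames(rep("unclassified", length(all_codes)), all_codes)
  for (i in seq_len(nrow(ranges))) {
    hit <- all_codes >= ranges$start[i] & all_codes <= ranges$end[i]
    lookup[hit] <- ranges$chapter[i]
  }
  lookup
}

validate_rules <- function(rules) {
  if (!inherits(rules, "classification_rules")) {
    stop("`rules` must be built by `default_classification_rules()` or compatible", call. = FALSE)
  }
  rules
}

#' Map ICD-10 codes to chapter labels
#'
#' @param code Character vector of ICD-10 codes (letter + two digits, optional
#'   decimal extension, e.g. `"J18"` or `"J18.9"`). `NA` or empty codes map to
#'   `"unclassified"` (records without a disease code stay in the money totals).
#' @param rules Classification rules from [default_classification_rules()].
#' @return Character vector of chapter labels; syntactically valid but
#'   uncovered codes return `"unclassified"`.
#' @export
icd10_chapter <- function(code, rules = default_classification_rules()) {
  validate_rules(rules)
  code <- toupper(trimws(as.character(code)))
  out <- rep("unclassified", length(code))
  missing <- is.na(code) | code == ""
  valid <- !missing & grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", code)
  if (any(!valid & !missing)) {
    bad <- unique(code[!valid & !missing])
    stop("invalid ICD-10 code(s): ", paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out[valid] <- unname(rules$chapter_lookup[substr(code[valid], 1, 3)])
  out
}

#' Map chapter labels to GBD broad cause groups
#'
#' @param chapter Character vector of chapter labels as returned by
#'   [icd10_chapter()]; `"unclassified"` passes through unchanged.
#' @inheritParams icd10_chapter
#' @return Character vector over the three GBD groups (or `"unclassified"`).
#' @export
gbd_group <- function(chapter, rules = default_classification_rules()) {
  validate_rules(rules)
  out <- rep(NA_character_, length(chapter))
  out[chapter == "unclassified"] <- "unclassified"
  known <- chapter %in% names(rules$gbd_group_map)
  out[known] <- unname(rules$gbd_group_map[chapter[known]])
  if (anyNA(out)) {
    bad <- unique(chapter[is.na(out)])
    stop("unknown chapter label(s): ", paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Map integer ages to age-bin labels
#'
#' Bins are half-open `[lower, upper)` intervals over integer years.
#'
#' @param age_years Integer vector of ages.
#' @inheritParams icd10_chapter
#' @return Character vector of bin labels.
#' @export
age_bin <- function(age_years, rules = default_classification_rules()) {
  validate_rules(rules)
  bins <- rules$age_bins
  idx <- findInterval(age_years, bins$lower)
  ok <- idx >= 1 & !is.na(age_years) & age_years < bins$upper[pmax(idx, 1)]
  if (any(!ok)) {
    stop("age(s) outside the covered bins: ",
         paste(head(unique(age_years[!ok]), 5), collapse = ", "), call. = FALSE)
  }
  bins$label[idx]
}

# Age labels used by the accounts engine: the rule bins for the child scope
# plus a "15+" bin so the full-population cube covers every age.
engine_age_label <- function(age_years, rules) {
  bins <- rules$age_bins
  top <- max(bins$upper)
  out <- rep("15+", length(age_years))
  inside <- age_years < top
  if (any(inside)) out[inside] <- age_bin(age_years[inside], rules)
  out
}

child_age_labels <- function(rules) rules$age_bins$label

#' Read / write classification rules as a versioned YAML document
#'
#' The rule set (chapter ranges, GBD group map, age bins) ships with the
#' package as `extdata/classification_rules_v1.yaml`; users can edit a copy
#' (e.g. to redefine the "Death" rows R95--R99 or the GBD mapping) and load
#' it here.
#'
#' @param path YAML file path; defaults to the packaged v1 rules.
#' @return A `classification_rules` object.
#' @export
read_classification_rules <- function(path = system.file(
  "extdata", "classification_rules_v1.yaml", package = "checounts")) {
  doc <- yaml::read_yaml(path)
  ranges <- dplyr::bind_rows(lapply(doc$icd_chapter_ranges, tibble::as_tibble))
  bins <- dplyr::bind_rows(lapply(doc$age_bins, tibble::as_tibble))
  gbd <- unlist(doc$gbd_group_map)
  missing <- setdiff(unique(ranges$chapter), names(gbd))
  if (length(missing) > 0) {
    stop("gbd_group_map misses chapter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(ranges$start > ranges$end)) {
    stop("invalid chapter range (start > end)", call. = FALSE)
  }
  rules <- list(icd_chapter_ranges = ranges, gbd_group_map = gbd,
                age_bins = bins)
  rules$chapter_lookup <- build_chapter_lookup(ranges)
  structure(rules, class = "classification_rules")
}

#' @rdname read_classification_rules
#' @param rules A `classification_rules` object.
#' @param version Version string recorded in the document.
#' @export
write_classification_rules <- function(rules, path, version = "1") {
  validate_rules(rules)
  doc <- list(
    version = version,
    icd_chapter_ranges = lapply(seq_len(nrow(rules$icd_chapter_ranges)),
      function(i) as.list(rules$icd_chapter_ranges[i, ])),
    gbd_group_map = as.list(rules$gbd_group_map),
    age_bins = lapply(seq_len(nrow(rules$age_bins)),
      function(i) as.list(rules$age_bins[i, ]))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
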