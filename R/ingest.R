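# Survey ingest: read, validate and normalize the three record families
# (patient encounters, institution finance sheets, provincial aggregates).
# Money is carried in CNY at full precision throughout; conversion to USD
# happens only in reporting.

payer_cols <- paste0("pay_", che_payer_categories)

encounter_cols <- c(
  "institution_id", "age_years", "sex", "icd10_code", "service_type",
  "bed_days", "total_cost", payer_cols
)

finance_cols <- c(
  "institution_id", "provider_type", "city",
  "outpatient_income", "preventive_outpatient_income", "inpatient_income",
  "basic_subsidy", "outpatient_project_subsidy", "inpatient_project_subsidy",
  "superior_institution_subsidy", "science_education_income", "other_income",
  "assistant_service_cost", "medicine_cost", "management_cost",
  "capital_expenditure"
)

read_family <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

ingest_result <- function(records, rejects, rows_read) {
  list(
    records = records,
    rejects = rejects,
    summary = list(
      rows_read = rows_read,
      rows_kept = nrow(records),
      rows_rejected = nrow(rejects)
    )
  )
}

#' Read patient encounter records
#'
#' Reads a comma-separated encounter file (one service contact per line) and
#' validates every row. Invalid rows are not dropped silently: they are
#' returned in a rejection table with the physical line number and reason, and
#' `rows_kept + rows_rejected = rows_read` always holds. Encounters with a
#' missing disease code are kept (they still carry money) and classified to
#' the explicit `"unclassified"` disease bin downstream.
#'
#' Checked invariants: age in 0--120; known service type; non-negative cost
#' and bed days; bed days only on inpatient records; payer-split components
#' summing to the total cost within `1e-6` relative tolerance; parseable
#' ICD-10 code when present.
#'
#' @param path Path to the CSV file. Columns: `institution_id`, `age_years`,
#'   `sex`, `icd10_code`, `service_type`, `bed_days`, `total_cost`, and one
#'   `pay_<category>` column per payer category.
#' @return A list with `records` (tibble of valid encounters), `rejects`
#'   (tibble: `line`, `reason`) and `summary` (rows read/kept/rejected).
#' @export
read_encounters <- function(path) {
  df <- read_family(path, encounter_cols)
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    flag <- function(bad, why) {
      bad[is.na(bad)] <- TRUE
      reason[is.na(reason) & bad] <<- why
    }
    flag(is.na(df$age_years) | df$age_years < 0 | df$age_years > 120 |
           df$age_years != floor(df$age_years), "invalid age")
    flag(!(df$service_type %in% che_service_types), "unknown service type")
    flag(is.na(df$total_cost) | df$total_cost < 0, "negative or missing cost")
    flag(is.na(df$bed_days) | df$bed_days < 0 | df$bed_days != floor(df$bed_days),
         "invalid bed days")
    flag(df$bed_days > 0 & df$service_type != "inpatient",
         "bed days on non-inpatient record")
    pay_sum <- rowSums(as.matrix(df[payer_cols]))
    flag(apply(as.matrix(df[payer_cols]) < 0, 1, any), "negative payer component")
    flag(abs(pay_sum - df$total_cost) > 1e-6 * pmax(df$total_cost, 1),
         "payer split mismatch")
    code_ok <- vapply(df$icd10_code, function(cd) {
      if (is.na(cd) || cd == "") return(TRUE)
      grepl("^[A-Za-z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$", trimws(cd))
    }, logical(1))
    flag(!code_ok, "unparseable ICD-10 code")
  }
  keep <- is.na(reason)
  records <- tibble::as_tibble(df[keep, encounter_cols])
  records$bed_days <- as.integer(records$bed_days)
  records$age_years <- as.integer(records$age_years)
  rejects <- tibble::tibble(
    line = which(!keep) + 1L, # header is physical line 1
    reason = reason[!keep]
  )
  ingest_result(records, rejects, n)
}

#' Write patient encounter records
#' @param records Tibble of encounters (as in `read_encounters()$records`).
#' @param path Output CSV path.
#' @export
write_encounters <- function(records, path) {
  readr::write_csv(records[encounter_cols], path)
  invisible(path)
}

#' Read institution finance sheets
#'
#' Reads annual finance sheets (one institution per line) and, optionally, a
#' companion long-format table of prevention projects
#' (`institution_id`, `project_id`, `income`, `expense`). Capital expenditure
#' is retained on the record but excluded from CHE by the accounts engine
#' (fixed-asset spending is outside current health expenditure).
#'
#' @param path Path to the finance CSV.
#' @param projects_path Optional path to the prevention-projects CSV.
#' @return As [read_encounters()]: `records`, `rejects`, `summary`; the
#'   records tibble carries a `projects` list-column.
#' @export
read_institution_finance <- function(path, projects_path = NULL) {
  df <- read_family(path, finance_cols)
  n <- nrow(df)
  money_cols <- setdiff(finance_cols, c("institution_id", "provider_type", "city"))
  reason <- rep(NA_character_, n)
  if (n > 0) {
    flag <- function(bad, why) {
      bad[is.na(bad)] <- TRUE
      reason[is.na(reason) & bad] <<- why
    }
    flag(!(df$provider_type %in% che_provider_types), "unknown provider type")
    flag(apply(as.matrix(df[money_cols]) < 0, 1, any) |
           apply(is.na(as.matrix(df[money_cols])), 1, any),
         "negative or missing money field")
    flag(df$preventive_outpatient_income > df$outpatient_income,
         "preventive income exceeds outpatient income")
    flag(duplicated(df$institution_id), "duplicate institution id")
  }
  keep <- is.na(reason)
  records <- tibble::as_tibble(df[keep, finance_cols])
  projects <- if (!is.null(projects_path)) {
    pr <- read_family(projects_path, c("institution_id", "project_id", "income", "expense"))
    if (any(pr$income < 0 | pr$expense < 0, na.rm = TRUE)) {
      stop("negative prevention project income/expense in ", projects_path, call. = FALSE)
    }
    pr
  } else {
    tibble::tibble(institution_id = character(), project_id = character(),
                   income = numeric(), expense = numeric())
  }
  records$projects <- lapply(records$institution_id, function(id) {
    projects[projects$institution_id == id, c("project_id", "income", "expense")]
  })
  rejects <- tibble::tibble(line = which(!keep) + 1L, reason = reason[!keep])
  ingest_result(records, rejects, n)
}

#' Write institution finance sheets
#'
#' @param records Finance tibble (`projects` list-column allowed; written to
#'   the companion file).
#' @param path Output CSV path for the flat sheet.
#' @param projects_path Optional output CSV path for prevention projects.
#' @export
write_institution_finance <- function(records, path, projects_path = NULL) {
  readr::write_csv(records[finance_cols], path)
  if (!is.null(projects_path)) {
    pr <- flatten_projects(records)
    readr::write_csv(pr, projects_path)
  }
  invisible(path)
}

flatten_projects <- function(institutions) {
  if (!"projects" %in% names(institutions)) {
    return(tibble::tibble(institution_id = character(), project_id = character(),
                          income = numeric(), expense = numeric()))
  }
  keep <- vapply(institutions$projects, function(p) !is.null(p) && nrow(p) > 0, logical(1))
  if (!any(keep)) {
    return(tibble::tibble(institution_id = character(), project_id = character(),
                          income = numeric(), expense = numeric()))
  }
  dplyr::bind_rows(lapply(which(keep), function(i) {
    dplyr::mutate(institutions$projects[[i]],
                  institution_id = institutions$institution_id[i], .before = 1)
  }))
}

provincial_stratum_keys <- c(
  "provider_type", "outpatient_income", "inpatient_income",
  "outpatient_visits", "inpatient_bed_days", "basic_subsidy",
  "outpatient_project_subsidy", "inpatient_project_subsidy"
)

#' Construct provincial aggregates
#'
#' The yearbook-level totals that the top-down method scales: per
#' provider-type stratum, total outpatient/inpatient income, visit and bed-day
#' counts, and basic/project subsidies.
#'
#' @param strata Tibble with columns `provider_type`, `outpatient_income`,
#'   `inpatient_income`, `outpatient_visits`, `inpatient_bed_days`,
#'   `basic_subsidy`, `outpatient_project_subsidy`,
#'   `inpatient_project_subsidy`.
#' @param exchange_rate_cny_per_usd Positive exchange rate (CNY per USD);
#'   default 6.20, the 2014 annual average.
#' @param year Accounting year.
#' @return Object of class `provincial_aggregates`.
#' @export
provincial_aggregates <- function(strata, exchange_rate_cny_per_usd = 6.20,
                                  year = NA_integer_) {
  strata <- tibble::as_tibble(strata)
  missing <- setdiff(provincial_stratum_keys, names(strata))
  if (length(missing) > 0) {
    stop("schema error: missing stratum key(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(provincial_stratum_keys, "provider_type")
  if (any(is.na(as.matrix(strata[num_cols]))) || any(as.matrix(strata[num_cols]) < 0)) {
    stop("schema error: negative or missing value in provincial strata", call. = FALSE)
  }
  bad <- setdiff(strata$provider_type, che_provider_types)
  if (length(bad) > 0) {
    stop("schema error: unknown provider type(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(exchange_rate_cny_per_usd) || exchange_rate_cny_per_usd <= 0) {
    stop("schema error: exchange_rate_cny_per_usd must be positive", call. = FALSE)
  }
  structure(
    list(strata = strata[provincial_stratum_keys],
         exchange_rate_cny_per_usd = exchange_rate_cny_per_usd,
         year = year),
    class = "provincial_aggregates"
  )
}

#' Read / write provincial aggregates as a YAML document
#'
#' A document missing the exchange rate falls back to 6.20 CNY per USD (the
#' 2014 annual average) with a warning.
#'
#' @param path YAML file path.
#' @return `read_provincial` returns a [provincial_aggregates()] object.
#' @export
read_provincial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$strata)) stop("schema error: missing key 'strata'", call. = FALSE)
  strata <- dplyr::bind_rows(lapply(doc$strata, tibble::as_tibble))
  rate <- doc$exchange_rate_cny_per_usd
  if (is.null(rate)) {
    warning("exchange_rate_cny_per_usd missing; defaulting to 6.20 CNY/USD")
    rate <- 6.20
  }
  provincial_aggregates(strata, rate, doc$year %||% NA_integer_)
}

#' @rdname read_provincial
#' @param provincial A [provincial_aggregates()] object.
#' @export
write_provincial <- function(provincial, path) {
  doc <- list(
    year = as.integer(provincial$year),
    exchange_rate_cny_per_usd = provincial$exchange_rate_cny_per_usd,
    strata = lapply(seq_len(nrow(provincial$strata)), function(i) {
      as.list(provincial$strata[i, ])
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
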