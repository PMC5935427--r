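# Reporting: render the accounts cube into the three standard table shapes
# (spending by provider category, disease-by-age percentage matrix, financing
# sources) and the GBD-by-age series, with late currency conversion and
# half-up rounding. All totals are computed from unrounded values and rounded
# only at the very end; each renderer attaches the unrounded table as an
# attribute.

#' Convert CNY amounts to USD
#'
#' @param amount_cny Amount(s) in CNY.
#' @param rate_cny_per_usd Positive exchange rate (CNY per USD).
#' @return Amount(s) in USD at full precision (round only when rendering).
#' @export
convert_currency <- function(amount_cny, rate_cny_per_usd) {
  if (!is.numeric(rate_cny_per_usd) || length(rate_cny_per_usd) != 1 ||
      is.na(rate_cny_per_usd) || rate_cny_per_usd <= 0) {
    stop("exchange rate must be a positive number", call. = FALSE)
  }
  amount_cny / rate_cny_per_usd
}

#' Round half-up to a fixed number of decimals
#'
#' Commercial rounding (0.005 -> 0.01), as used in the printed tables, unlike
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Default mapping from provider strata to report rows
#'
#' Primary health agents aggregate township hospitals, community health
#' centers and village/individual clinics; hospitals split into general
#' (province-level hospitals included), specialized and traditional Chinese
#' medicine sub-rows.
#'
#' @return Tibble with `provider_type`, `row`, `subrow`.
#' @export
default_provider_report_map <- function() {
  tibble::tribble(
    ~provider_type, ~row, ~subrow,
    "township_hospital", "Primary health agents", NA,
    "community_health_center", "Primary health agents", NA,
    "village_or_individual_clinic", "Primary health agents", NA,
    "outpatient_service_institution", "Outpatient service institutions", NA,
    "maternal_child_center", "Maternal and child care centers", NA,
    "provincial_hospital", "Hospitals:", "general hospital",
    "general_hospital", "Hospitals:", "general hospital",
    "specialized_hospital", "Hospitals:", "specialized hospital",
    "tcm_hospital", "Hospitals:", "traditional Chinese medical hospital",
    "public_health_institution", "Public health institutions", NA
  )
}

cube_in_units <- function(cube, rate, unit) {
  x <- tibble::as_tibble(cube)
  r <- if (is.null(rate)) 1 else rate
  if (!is.null(rate)) r <- {
    convert_currency(1, rate) # validates
    rate
  }
  x$amount <- x$amount_cny / r / unit
  x
}

#' Render the spending-by-provider table
#'
#' One row per provider category with outpatient, inpatient and total
#' columns; hospitals carry general/specialized/TCM sub-rows that sum to the
#' parent row. The inpatient column holds the curative inpatient function;
#' every other function (outpatient curative care, prevention, assistant
#' services, medicine, management) is outpatient-delivered and lands in the
#' outpatient column.
#'
#' @param cube An [accounts_cube()] (CNY).
#' @param rate Exchange rate CNY per USD; `NULL` keeps CNY.
#' @param unit Reporting unit divisor (default `1e6`: millions).
#' @param digits Decimals for half-up rounding.
#' @param provider_map See [default_provider_report_map()].
#' @return Tibble with `row`, `outpatient`, `inpatient`, `total`, `level`
#'   (`"row"`/`"subrow"`); the unrounded table is in `attr(, "unrounded")`.
#' @export
render_provider_table <- function(cube, rate = NULL, unit = 1e6, digits = 2,
                                  provider_map = default_provider_report_map()) {
  x <- cube_in_units(cube, rate, unit)
  unmapped <- setdiff(unique(x$provider_type), provider_map$provider_type)
  if (length(unmapped) > 0) {
    stop("unmapped provider stratum: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::left_join(x, provider_map, by = "provider_type")
  x$column <- ifelse(x$fn == "curative_inpatient", "inpatient", "outpatient")
  agg <- function(df, keys) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$column) |>
      dplyr::summarise(amount = sum(.data$amount), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "column", values_from = "amount",
                         values_fill = 0)
  }
  fill_cols <- function(df) {
    for (cc in c("outpatient", "inpatient")) if (!cc %in% names(df)) df[[cc]] <- 0
    df$total <- df$outpatient + df$inpatient
    df
  }
  rows <- fill_cols(agg(x, "row"))
  subrows <- fill_cols(agg(x[!is.na(x$subrow), ], c("row", "subrow")))
  core <- c("Primary health agents", "Outpatient service institutions",
            "Maternal and child care centers", "Hospitals:")
  row_order <- c(core, setdiff(unique(provider_map$row), core))
  out <- list()
  for (rw in row_order) {
    r <- rows[rows$row == rw, ]
    if (nrow(r) == 0) {
      if (!rw %in% core) next
      r <- tibble::tibble(row = rw, outpatient = 0, inpatient = 0, total = 0)
    }
    out[[length(out) + 1]] <- tibble::tibble(
      row = rw, outpatient = r$outpatient, inpatient = r$inpatient,
      total = r$total, level = "row"
    )
    sr <- subrows[subrows$row == rw, ]
    if (nrow(sr) > 0) {
      sr <- sr[order(match(sr$subrow, unique(provider_map$subrow))), ]
      out[[length(out) + 1]] <- tibble::tibble(
        row = sr$subrow, outpatient = sr$outpatient, inpatient = sr$inpatient,
        total = sr$total, level = "subrow"
      )
    }
  }
  tab <- dplyr::bind_rows(out)
  res <- tab
  for (cc in c("outpatient", "inpatient", "total")) {
    res[[cc]] <- round_half_up(res[[cc]], digits)
  }
  attr(res, "unrounded") <- tab
  res
}

#' Render the disease-by-age percentage matrix
#'
#' Rows are ICD-10 chapter labels, columns the child scope total (`"0-14"`)
#' and the single-year bins; each cell is the chapter's percentage of its
#' column's spending. The inclusive overflow bin (age 14) is folded into the
#' scope total but not shown as its own column. A column with zero spending
#' renders as `NA` with a warning.
#'
#' @param cube A child-scope [accounts_cube()].
#' @param rules Classification rules.
#' @param digits Decimals for half-up rounding.
#' @return Tibble: `disease_class` plus one column per age bin; unrounded
#'   percentages in `attr(, "unrounded")`.
#' @export
render_disease_age_matrix <- function(cube, rules = default_classification_rules(),
                                      digits = 2) {
  bins <- rules$age_bins
  show_bins <- bins$label[!bins$overflow]
  all_label <- paste0(min(bins$lower), "-", max(bins$upper) - 1)
  m <- cube_margin(cube, "disease_class", "age_bin")
  m <- m[m$age_bin %in% bins$label, ]
  chapters <- c(unique(rules$icd_chapter_ranges$chapter), "unclassified")
  chapters <- chapters[chapters %in% unique(m$disease_class)]
  empty_cols <- character()
  wide <- function(mm, label) {
    tot <- sum(mm$amount_cny)
    if (tot <= 0) {
      empty_cols <<- c(empty_cols, label)
      return(rep(NA_real_, length(chapters)))
    }
    agg <- tapply(mm$amount_cny, factor(mm$disease_class, levels = chapters),
                  sum, default = 0)
    as.numeric(100 * agg / tot)
  }
  cols <- list(wide(m, all_label))
  names(cols) <- all_label
  for (b in show_bins) {
    cols[[b]] <- wide(m[m$age_bin == b, ], b)
  }
  if (length(empty_cols) > 0) {
    warning("zero spending in column(s) ", paste(empty_cols, collapse = ", "),
            "; rendered as NA")
  }
  tab <- tibble::as_tibble(c(list(disease_class = chapters), cols))
  res <- tab
  for (cc in names(cols)) res[[cc]] <- round_half_up(res[[cc]], digits)
  attr(res, "unrounded") <- tab
  res
}

#' Render the financing-sources table
#'
#' The funding-schemes shape: financial subsidy (with basic and project
#' sub-rows), superior-institution subsidy, medical income, science and
#' education income, others, and a total computed from unrounded components.
#'
#' @param x An [accounts_cube()] carrying financing-source metadata, or a
#'   tibble with `source` and `amount_cny` columns.
#' @param rate Exchange rate CNY per USD; `NULL` keeps CNY.
#' @param unit Reporting unit divisor (default `1e6`).
#' @param digits Decimals for half-up rounding.
#' @return Tibble with `row`, `amount`, `level`; unrounded amounts in
#'   `attr(, "unrounded")`.
#' @export
render_financing_table <- function(x, rate = NULL, unit = 1e6, digits = 2) {
  sources <- if (inherits(x, "accounts_cube")) attr(x, "sources") else x
  if (is.null(sources)) stop("cube carries no financing-source metadata", call. = FALSE)
  r <- if (is.null(rate)) 1 else rate
  if (!is.null(rate)) convert_currency(1, rate)
  s <- tapply(sources$amount_cny / r / unit,
              factor(sources$source, levels = c(
                "basic_subsidy", "project_subsidy",
                "superior_institution_subsidy", "medical_income",
                "science_education_income", "others"
              )), sum, default = 0)
  tab <- tibble::tibble(
    row = c("Financial subsidy:", "basic subsidy", "project subsidy",
            "Superior institution subsidy (only primary medical institutions)",
            "Medical income", "Science and education income (only hospitals)",
            "Others", "Total"),
    amount = c(
      s[["basic_subsidy"]] + s[["project_subsidy"]],
      s[["basic_subsidy"]], s[["project_subsidy"]],
      s[["superior_institution_subsidy"]], s[["medical_income"]],
      s[["science_education_income"]], s[["others"]],
      sum(s)
    ),
    level = c("row", "subrow", "subrow", "row", "row", "row", "row", "total")
  )
  res <- tab
  res$amount <- round_half_up(res$amount, digits)
  attr(res, "unrounded") <- tab
  res
}

#' GBD broad-cause shares by age bin
#'
#' The Figure-1-style series: within each child age bin (and the scope
#' total), the percentage of spending in each GBD broad cause group.
#'
#' @param cube A child-scope [accounts_cube()].
#' @param rules Classification rules.
#' @param digits Decimals for half-up rounding.
#' @return Tibble with `age_bin`, `gbd_group`, `percent`.
#' @export
render_gbd_age_series <- function(cube, rules = default_classification_rules(),
                                  digits = 2) {
  bins <- rules$age_bins
  all_label <- paste0(min(bins$lower), "-", max(bins$upper) - 1)
  m <- cube_margin(cube, "disease_class", "age_bin")
  m <- m[m$age_bin %in% bins$label, ]
  m$gbd_group <- gbd_group(m$disease_class, rules)
  per_bin <- m |>
    dplyr::group_by(.data$age_bin, .data$gbd_group) |>
    dplyr::summarise(amount = sum(.data$amount_cny), .groups = "drop_last") |>
    dplyr::mutate(percent = 100 * .data$amount / sum(.data$amount)) |>
    dplyr::ungroup()
  overall <- m |>
    dplyr::group_by(.data$gbd_group) |>
    dplyr::summarise(amount = sum(.data$amount_cny), .groups = "drop") |>
    dplyr::mutate(age_bin = all_label,
                  percent = 100 * .data$amount / sum(.data$amount))
  out <- dplyr::bind_rows(overall[c("age_bin", "gbd_group", "percent")],
                          per_bin[c("age_bin", "gbd_group", "percent")])
  out$percent <- round_half_up(out$percent, digits)
  out
}

#' Run the whole accounting pipeline
#'
#' Orchestrates generation (or ingest), coefficient estimation, the top-down
#' accounts computation, the children restriction, and table rendering. Any
#' stage failure aborts with the stage name and cause. A log records every
#' coefficient and switch in effect.
#'
#' @param config A list with either `generator` (a [generator_config()],
#'   optionally `plan`, a [sampling_plan()], and `survey_seed`) or `paths`
#'   (named list: `encounters`, `institutions`, `projects`, `provincial`),
#'   plus optional `kappa`, `prevention_rule`, `n_ibd_source`, `rules`,
#'   `target_age_max`, and `out` (output directory).
#' @return List of class `che_pipeline`: `coefficients`, `cube_total`
#'   (full population), `cube_children`, `tables` (provider, disease_age,
#'   financing, gbd_age), `provincial`, `log`; invisibly written to
#'   `config$out` when given.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  rules <- config$rules %||% default_classification_rules()
  kappa <- config$kappa %||% 0.1
  prevention_rule <- config$prevention_rule %||% "max"
  n_ibd_source <- config$n_ibd_source %||% "provincial"
  target_age_max <- config$target_age_max %||% 14

  inputs <- stage("ingest", {
    if (!is.null(config$generator)) {
      ds <- generate_dataset(config$generator)
      survey <- if (!is.null(config$plan)) {
        draw_survey(ds, config$plan, seed = config$survey_seed %||% 1L)
      } else {
        ds
      }
      say("generated census: %d institutions, %d encounters; survey: %d institutions, %d encounters",
          nrow(ds$institutions), nrow(ds$encounters),
          nrow(survey$institutions), nrow(survey$encounters))
      list(encounters = survey$encounters, institutions = survey$institutions,
           provincial = ds$provincial, census = ds)
    } else {
      p <- config$paths
      for (key in c("encounters", "institutions", "provincial")) {
        if (is.null(p[[key]]) || !file.exists(p[[key]])) {
          stop("missing input file for '", key, "': ",
               p[[key]] %||% "<unset>", call. = FALSE)
        }
      }
      enc <- read_encounters(p$encounters)
      inst <- read_institution_finance(p$institutions, p$projects)
      say("read %d encounters (%d rejected), %d institutions (%d rejected)",
          enc$summary$rows_kept, enc$summary$rows_rejected,
          inst$summary$rows_kept, inst$summary$rows_rejected)
      list(encounters = enc$records, institutions = inst$records,
           provincial = read_provincial(p$provincial), census = NULL)
    }
  })

  coefficients <- stage("coefficients", {
    tl <- tally_survey(inputs$encounters, inputs$institutions, target_age_max)
    estimate_coefficients(tl, inputs$provincial, kappa = kappa,
                          n_ibd_source = n_ibd_source)
  })
  say("pooled coefficients: alpha_i=%.6f alpha_s=%.6f upsilon=%.6f beta=%.6f kappa=%.3f (N_IBD source: %s)",
      coefficients$pooled$alpha_i, coefficients$pooled$alpha_s,
      coefficients$pooled$upsilon, coefficients$pooled$beta, kappa, n_ibd_source)
  say("prevention rule: %s; child age cutoff: %d (inclusive)",
      prevention_rule, target_age_max)

  cube_pop <- stage("accounts", {
    compute_che(inputs$provincial, inputs$encounters, inputs$institutions,
                coefficients, rules, prevention_rule = prevention_rule)
  })
  cube_children <- stage("accounts", restrict_to_children(cube_pop, rules))
  say("CHE total population: %.2f CNY; children scope: %.2f CNY (%.4f%%)",
      cube_total(cube_pop), cube_total(cube_children),
      100 * cube_total(cube_children) / cube_total(cube_pop))

  rate <- inputs$provincial$exchange_rate_cny_per_usd
  tables <- stage("reporting", list(
    provider = render_provider_table(cube_children, rate = rate),
    disease_age = render_disease_age_matrix(cube_children, rules),
    financing = render_financing_table(cube_children, rate = rate),
    gbd_age = render_gbd_age_series(cube_children, rules)
  ))

  result <- structure(
    list(coefficients = coefficients, cube_total = cube_pop,
         cube_children = cube_children, tables = tables,
         provincial = inputs$provincial, census = inputs$census, log = log),
    class = "che_pipeline"
  )
  if (!is.null(config$out)) {
    stage("output", {
      dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
      write_cube(cube_pop, file.path(config$out, "cube_total_population.csv"))
      write_cube(cube_children, file.path(config$out, "cube_children.csv"))
      write_coefficients(coefficients, file.path(config$out, "coefficients.yaml"))
      readr::write_csv(tables$provider, file.path(config$out, "table_provider.csv"))
      readr::write_csv(tables$disease_age, file.path(config$out, "table_disease_age.csv"))
      readr::write_csv(tables$financing, file.path(config$out, "table_financing.csv"))
      readr::write_csv(tables$gbd_age, file.path(config$out, "figure_gbd_age.csv"))
      writeLines(log, file.path(config$out, "pipeline_log.txt"))
    })
  }
  result
}
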