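# The top-down accounts engine.
#
# Provincial financial aggregates are scaled into the accounts cube using the
# survey-derived coefficients, per provider-type stratum:
#
#   E_OCI = E_OI * alpha_i          curative outpatient income
#   E_BCS = E_BS * alpha_s          basic curative expenditure subsidy
#   E_OBS = E_BCS * (1 - beta)      its outpatient share
#   E_IBS = E_BCS * beta            its inpatient share
#   E_OCS = E_OCI + E_OPS + E_OBS   outpatient curative total
#   E_ICS = E_ICI + E_IPS + E_IBS   inpatient curative total
#
# Inpatient curative income takes the provincial inpatient income without a
# preventive deduction (only the outpatient side has preventive activity to
# remove). The preventive remainder E_OI * (1 - alpha_i) is booked under the
# prevention function so that money is conserved. Prevention projects,
# assistant services, medicine and management costs are taken from the survey
# finance sheets and scaled to the province by the stratum income ratio
# r(s) = provincial income(s) / survey income(s). Capital expenditure never
# enters the cube (outside CHE).
#
# Disease, age and financing detail is filled by allocating each stratum
# amount proportionally to the survey's encounter-level cost cells within the
# matching (stratum, service type); payer components map onto financing
# schemes as: government programs and subsidies -> government; social and
# commercial insurance and donations -> social; out-of-pocket -> household.

#' Curative outpatient income per stratum (E_OCI = E_OI x alpha_i)
#'
#' @param provincial A [provincial_aggregates()] object.
#' @param alpha_i Curative share of outpatient income: a scalar, or a vector
#'   named by provider type.
#' @return Tibble with `provider_type` and `e_oci`.
#' @export
curative_outpatient_income <- function(provincial, alpha_i) {
  a <- resolve_per_stratum(alpha_i, provincial$strata$provider_type, "alpha_i")
  if (any(a < 0 | a > 1)) stop("alpha_i must lie in [0, 1]", call. = FALSE)
  tibble::tibble(
    provider_type = provincial$strata$provider_type,
    e_oci = provincial$strata$outpatient_income * a
  )
}

resolve_per_stratum <- function(x, strata, what) {
  if (length(x) == 1 && is.null(names(x))) return(rep(as.numeric(x), length(strata)))
  if (is.null(names(x)) && length(x) == length(strata)) return(as.numeric(x))
  if (!all(strata %in% names(x))) {
    stop("missing ", what, " for stratum: ",
         paste(setdiff(strata, names(x)), collapse = ", "), call. = FALSE)
  }
  as.numeric(x[strata])
}

#' Split the basic subsidy into curative outpatient and inpatient shares
#'
#' `E_BCS = E_BS * alpha_s`, `E_OBS = E_BCS * (1 - beta)`,
#' `E_IBS = E_BCS * beta`; the two shares sum to `E_BCS` exactly.
#'
#' @param e_bs Basic expenditure subsidy (vectorized).
#' @param alpha_s,beta Proportions in `[0, 1]` (vectorized).
#' @return Tibble with `e_bcs`, `e_obs`, `e_ibs`.
#' @export
split_basic_subsidy <- function(e_bs, alpha_s, beta) {
  if (any(alpha_s < 0 | alpha_s > 1) || any(beta < 0 | beta > 1)) {
    stop("alpha_s and beta must lie in [0, 1]", call. = FALSE)
  }
  e_bcs <- e_bs * alpha_s
  tibble::tibble(e_bcs = e_bcs, e_obs = e_bcs * (1 - beta), e_ibs = e_bcs * beta)
}

#' Assemble curative account totals per stratum
#'
#' @param provincial A [provincial_aggregates()] object.
#' @param coefficients A `coefficient_set` from [estimate_coefficients()].
#' @return Tibble of class `curative_accounts` with, per stratum: `e_oci`,
#'   `e_ops`, `e_obs`, `e_ocs` (their sum), the inpatient analogues `e_ici`,
#'   `e_ips`, `e_ibs`, `e_ics`, and `e_bcs`.
#' @export
curative_totals <- function(provincial, coefficients) {
  prov <- provincial$strata
  cf <- stratum_coefficients(coefficients, prov$provider_type)
  oci <- curative_outpatient_income(provincial,
    setNames(cf$alpha_i, cf$provider_type))
  sub <- split_basic_subsidy(prov$basic_subsidy, cf$alpha_s, cf$beta)
  out <- tibble::tibble(
    provider_type = prov$provider_type,
    e_oci = oci$e_oci,
    e_ops = prov$outpatient_project_subsidy,
    e_obs = sub$e_obs,
    e_ici = prov$inpatient_income,
    e_ips = prov$inpatient_project_subsidy,
    e_ibs = sub$e_ibs,
    e_bcs = sub$e_bcs
  )
  out$e_ocs <- out$e_oci + out$e_ops + out$e_obs
  out$e_ics <- out$e_ici + out$e_ips + out$e_ibs
  class(out) <- c("curative_accounts", class(out))
  out
}

# coefficient rows aligned to the given strata, pooled values for strata the
# coefficient set has never seen
stratum_coefficients <- function(coefficients, strata) {
  idx <- match(strata, coefficients$by_stratum$provider_type)
  cf <- coefficients$by_stratum[idx, ]
  cf$provider_type <- strata
  for (col in c("alpha_i", "alpha_s", "upsilon", "beta")) {
    cf[[col]][is.na(cf[[col]])] <- coefficients$pooled[[col]]
  }
  cf$n_iov[is.na(cf$n_iov)] <- 0
  cf
}

#' Prevention expenditure from project income/expense comparisons
#'
#' Each government prevention project reports an income and an expense; the
#' accounted amount per project is the larger of the two under the default
#' rule (`"max"`): when income falls short of expense the service expense is
#' counted, otherwise the income. The alternative `"expense_always"` counts
#' the expense in both branches.
#'
#' @param projects Data frame with `income` and `expense` columns (one project
#'   per row); zero rows give zero.
#' @param rule `"max"` (default) or `"expense_always"`.
#' @return Total accounted prevention-project expenditure.
#' @export
prevention_expenditure <- function(projects, rule = c("max", "expense_always")) {
  rule <- match.arg(rule)
  if (is.null(projects) || nrow(projects) == 0) return(0)
  if (any(projects$income < 0 | projects$expense < 0, na.rm = TRUE) ||
      anyNA(projects$income) || anyNA(projects$expense)) {
    stop("prevention project income/expense must be non-negative", call. = FALSE)
  }
  if (rule == "max") sum(pmax(projects$income, projects$expense)) else sum(projects$expense)
}

#' Decompose an amount into financing schemes
#'
#' Subsidies (basic, project, superior) go to the government scheme; social
#' insurance, commercial insurance and donations to the social scheme;
#' out-of-pocket payments to the household scheme. Encounter payments are
#' decomposed by their payer split; `other_income` is treated as a social
#' source.
#'
#' @param amount_kind One of `"basic_subsidy"`, `"project_subsidy"`,
#'   `"superior_subsidy"`, `"encounter_payment"`, `"other_income"`.
#' @param amount Non-negative amount.
#' @param payer_split For `"encounter_payment"`: named numeric over the payer
#'   categories, summing to `amount`.
#' @return Tibble with `government`, `social`, `household` summing to
#'   `amount`.
#' @export
assign_financing <- function(amount_kind = c("basic_subsidy", "project_subsidy",
                                             "superior_subsidy",
                                             "encounter_payment", "other_income"),
                             amount, payer_split = NULL) {
  amount_kind <- match.arg(amount_kind)
  if (amount < 0) stop("amount must be non-negative", call. = FALSE)
  out <- c(government = 0, social = 0, household = 0)
  if (amount_kind == "encounter_payment") {
    if (is.null(payer_split)) stop("encounter_payment requires a payer_split", call. = FALSE)
    bad <- setdiff(names(payer_split), che_payer_categories)
    if (length(bad) > 0) stop("unknown payer categories: ", paste(bad, collapse = ", "), call. = FALSE)
    if (abs(sum(payer_split) - amount) > 1e-6 * max(amount, 1)) {
      stop("payer split does not sum to the amount", call. = FALSE)
    }
    for (p in names(payer_split)) {
      sc <- payer_scheme_map[[p]]
      out[sc] <- out[sc] + payer_split[[p]]
    }
  } else if (amount_kind == "other_income") {
    out["social"] <- amount
  } else {
    out["government"] <- amount
  }
  tibble::tibble(government = out[["government"]], social = out[["social"]],
                 household = out[["household"]])
}

# ---- encounter cell tables ------------------------------------------------

classify_encounters <- function(encounters, institutions, rules) {
  enc <- join_provider_type(encounters, institutions)
  enc$disease_class <- icd10_chapter(enc$icd10_code, rules)
  enc$age_lab <- engine_age_label(enc$age_years, rules)
  enc
}

# payer-level cell sums: (stratum, service, disease, age, payer) -> amount
payer_cell_table <- function(enc) {
  enc |>
    dplyr::select(dplyr::all_of(c("provider_type", "service_type",
                                  "disease_class", "age_lab", payer_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(payer_cols),
                        names_to = "payer", values_to = "amount") |>
    dplyr::mutate(payer = sub("^pay_", "", .data$payer)) |>
    dplyr::group_by(.data$provider_type, .data$service_type,
                    .data$disease_class, .data$age_lab, .data$payer) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop") |>
    dplyr::filter(.data$amount > 0)
}

# allocate per-stratum amounts over a weight table; weights may carry a payer
# column (financing follows the payer map) or not (fixed scheme applies).
# Strata absent from the weight table fall back to the pooled weights; if no
# weights exist at all the amount lands in a single unclassified cell.
allocate_by_weights <- function(amounts, weights, fn, fixed_scheme = NULL) {
  amounts <- amounts[amounts$amount > 0, ]
  if (nrow(amounts) == 0) return(NULL)
  has_payer <- "payer" %in% names(weights)
  pooled <- weights |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("disease_class", "age_lab", if (has_payer) "payer")))) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
  rows <- lapply(seq_len(nrow(amounts)), function(i) {
    s <- amounts$provider_type[i]
    amt <- amounts$amount[i]
    w <- weights[weights$provider_type == s, , drop = FALSE]
    w <- if (nrow(w) > 0 && sum(w$amount) > 0) w else pooled
    if (nrow(w) == 0 || sum(w$amount) <= 0) {
      w <- tibble::tibble(disease_class = "unclassified", age_lab = "15+",
                          amount = 1)
      if (has_payer) w$payer <- "out_of_pocket"
    }
    share <- w$amount / sum(w$amount)
    tibble::tibble(
      provider_type = s,
      fn = fn,
      financing = if (has_payer) unname(payer_scheme_map[w$payer]) else fixed_scheme,
      disease_class = w$disease_class,
      age_bin = w$age_lab,
      amount_cny = amt * share
    )
  })
  dplyr::bind_rows(rows)
}

per_stratum_sum <- function(df, col, strata) {
  agg <- df |>
    dplyr::group_by(.data$provider_type) |>
    dplyr::summarise(amount = sum(.data[[col]]), .groups = "drop")
  tibble::tibble(
    provider_type = strata,
    amount = ifelse(is.na(match(strata, agg$provider_type)), 0,
                    agg$amount[match(strata, agg$provider_type)])
  )
}

#' Compute the full-population CHE accounts cube top-down
#'
#' Scales the provincial aggregates with the coefficient set, fills the
#' disease, age and financing dimensions from the survey encounter cells, and
#' adds prevention, assistant-services, medicine and management expenditure
#' scaled from the survey finance sheets by the stratum income ratio. The
#' result covers the total population; restrict it with
#' [restrict_to_children()].
#'
#' @param provincial A [provincial_aggregates()] object.
#' @param encounters Survey encounter tibble.
#' @param institutions Survey institution finance tibble (with `projects`
#'   list-column for prevention projects).
#' @param coefficients A `coefficient_set`.
#' @param rules Classification rules.
#' @param prevention_rule Passed to [prevention_expenditure()].
#' @return An [accounts_cube()] in CNY with a financing-sources attribute.
#' @export
compute_che <- function(provincial, encounters, institutions, coefficients,
                        rules = default_classification_rules(),
                        prevention_rule = c("max", "expense_always")) {
  prevention_rule <- match.arg(prevention_rule)
  prov <- provincial$strata
  strata <- prov$provider_type
  enc <- classify_encounters(encounters, institutions, rules)
  w_pay <- payer_cell_table(enc)
  w_cost <- w_pay |>
    dplyr::group_by(.data$provider_type, .data$service_type,
                    .data$disease_class, .data$age_lab) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
  w_all_pay <- w_pay |>
    dplyr::group_by(.data$provider_type, .data$disease_class, .data$age_lab,
                    .data$payer) |>
    dplyr::summarise(amount = sum(.data$amount), .groups = "drop")
  svc <- function(w, s) w[w$service_type == s, setdiff(names(w), "service_type")]

  cur <- curative_totals(provincial, coefficients)
  cf <- stratum_coefficients(coefficients, strata)

  # survey income per stratum (finance sheets) -> province scaling ratio r(s)
  inst_income <- per_stratum_sum(
    dplyr::mutate(institutions,
                  income = .data$outpatient_income + .data$inpatient_income),
    "income", strata)
  prov_income <- prov$outpatient_income + prov$inpatient_income
  r_pooled <- if (sum(inst_income$amount) > 0) {
    sum(prov_income) / sum(inst_income$amount)
  } else {
    1
  }
  r <- ifelse(inst_income$amount > 0, prov_income / inst_income$amount, r_pooled)

  inst <- institutions
  inst$prev_proj <- vapply(inst$projects %||% rep(list(NULL), nrow(inst)),
                           prevention_expenditure, numeric(1),
                           rule = prevention_rule)
  amt <- function(x) tibble::tibble(provider_type = strata, amount = x)
  scaled <- function(col) {
    a <- per_stratum_sum(inst, col, strata)
    a$amount <- a$amount * r
    a
  }

  cells <- dplyr::bind_rows(
    allocate_by_weights(amt(cur$e_oci), svc(w_pay, "outpatient_curative"),
                        "curative_outpatient"),
    allocate_by_weights(amt(cur$e_ops + cur$e_obs),
                        svc(w_cost, "outpatient_curative"),
                        "curative_outpatient", fixed_scheme = "government"),
    allocate_by_weights(amt(cur$e_ici), svc(w_pay, "inpatient"),
                        "curative_inpatient"),
    allocate_by_weights(amt(cur$e_ips + cur$e_ibs), svc(w_cost, "inpatient"),
                        "curative_inpatient", fixed_scheme = "government"),
    allocate_by_weights(amt(prov$outpatient_income * (1 - cf$alpha_i)),
                        svc(w_pay, "outpatient_preventive"), "prevention"),
    # prevention projects plus the public-health share of the basic subsidy
    # E_BS * (1 - alpha_s): both are government prevention money
    allocate_by_weights({
      pp <- scaled("prev_proj")
      pp$amount <- pp$amount + (prov$basic_subsidy - cur$e_bcs)
      pp
    }, svc(w_cost, "outpatient_preventive"),
    "prevention", fixed_scheme = "government"),
    allocate_by_weights(scaled("assistant_service_cost"), w_all_pay,
                        "assistant_services"),
    allocate_by_weights(scaled("medicine_cost"), w_all_pay, "medicine"),
    allocate_by_weights(scaled("management_cost"), w_all_pay, "management")
  )

  sources <- financing_sources(prov, inst, r, strata)
  accounts_cube(cells,
    currency = "CNY", year = provincial$year,
    scope = "total_population", sources = sources
  )
}

# financing-source amounts (Table 3 shape), per stratum: provincial values
# where the yearbook has them, income-ratio-scaled survey values otherwise
financing_sources <- function(prov, inst, r, strata) {
  scaled <- function(col) {
    a <- per_stratum_sum(inst, col, strata)
    a$amount * r
  }
  tibble::tibble(
    provider_type = rep(strata, 6),
    source = rep(c("basic_subsidy", "project_subsidy",
                   "superior_institution_subsidy", "medical_income",
                   "science_education_income", "others"), each = length(strata)),
    amount_cny = c(
      prov$basic_subsidy,
      prov$outpatient_project_subsidy + prov$inpatient_project_subsidy,
      scaled("superior_institution_subsidy"),
      prov$outpatient_income + prov$inpatient_income,
      scaled("science_education_income"),
      scaled("other_income")
    )
  )
}

#' Restrict an accounts cube to the children subpopulation
#'
#' Keeps the cells whose age bin lies inside the child scope (ages up to and
#' including `target_age_max`, i.e. the single-year bins plus the inclusive
#' overflow bin). Because every cell was filled using survey cost shares at
#' (stratum, service, disease, age) resolution, dropping the adult bin is
#' arithmetically identical to scaling each (stratum, service) amount by its
#' survey children's cost share and re-filling disease/age detail from the
#' child-only shares. Financing-source metadata is scaled by each stratum's
#' realized children's share.
#'
#' @param cube An [accounts_cube()] with the full-population scope.
#' @param rules Classification rules (defines the child age bins).
#' @return An [accounts_cube()] with scope `"children_0_<target>"`.
#' @export
restrict_to_children <- function(cube, rules = default_classification_rules()) {
  child_bins <- child_age_labels(rules)
  cells <- tibble::as_tibble(cube)
  kept <- cells[cells$age_bin %in% child_bins, ]
  sources <- attr(cube, "sources")
  if (!is.null(sources)) {
    full <- cube_margin(cube, "provider_type")
    child <- kept |>
      dplyr::group_by(.data$provider_type) |>
      dplyr::summarise(amount_cny = sum(.data$amount_cny), .groups = "drop")
    ratio <- setNames(rep(0, nrow(full)), full$provider_type)
    ratio[child$provider_type] <- child$amount_cny /
      full$amount_cny[match(child$provider_type, full$provider_type)]
    sources$amount_cny <- sources$amount_cny *
      ifelse(is.na(ratio[sources$provider_type]), 0, ratio[sources$provider_type])
  }
  top <- max(rules$age_bins$upper) - 1
  accounts_cube(kept,
    currency = attr(cube, "currency"), year = attr(cube, "year"),
    scope = paste0("children_0_", top), sources = sources
  )
}
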