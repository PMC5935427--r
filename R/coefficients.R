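# Survey-derived allocation coefficients.
#
# The top-down method needs four proportions estimated from the institution
# survey before provincial aggregates can be scaled:
#   alpha_i = 1 - E_POI/E_TOI   share of outpatient income that is curative
#   alpha_s = N_MS/(N_MS+N_PHS) share of basic subsidy serving curative care
#                               (equivalent-person principle, child counts)
#   upsilon = 1 - N_POV/N_TOV   share of outpatient visits that are curative
#   beta    = N_IBD/(N_IBD + N_IOV*kappa)
#                               inpatient share of curative basic subsidy
#                               (equivalent-workload principle: one outpatient
#                               visit counts as kappa bed-day equivalents)
# with N_IOV = N_OV * upsilon, the provincial outpatient visit count with
# preventive visits removed. Coefficients are estimated per provider-type
# stratum with a pooled fallback for empty strata.

#' Tally survey records into the quantities the coefficient formulas need
#'
#' Computes, per provider-type stratum and pooled: preventive and total
#' outpatient income (E_POI, E_TOI), child medical-service and public-health
#' contact counts (N_MS, N_PHS), inpatient bed days (N_IBD), total and
#' preventive outpatient visit counts (N_TOV, N_POV), and the children's cost
#' share per stratum and service type. The child filter is
#' `age_years <= target_age_max`, inclusive (default 14: children are the
#' population aged 14 and below).
#'
#' @param encounters Encounter tibble (see [read_encounters()]).
#' @param institutions Institution finance tibble; used to map
#'   `institution_id` to `provider_type`.
#' @param target_age_max Inclusive upper age of the target subpopulation.
#' @return Object of class `survey_tallies`: list with `by_stratum` (tibble),
#'   `pooled` (one-row tibble), `children_cost_share` (tibble: provider_type,
#'   service_type, child_cost, total_cost, share) and `target_age_max`.
#' @export
tally_survey <- function(encounters, institutions, target_age_max = 14) {
  if (nrow(encounters) == 0) stop("no survey records", call. = FALSE)
  enc <- join_provider_type(encounters, institutions)
  is_out <- enc$service_type %in% c("outpatient_curative", "outpatient_preventive")
  is_prev <- enc$service_type == "outpatient_preventive"
  is_child <- enc$age_years <= target_age_max
  enc$w_e_toi <- enc$total_cost * is_out
  enc$w_e_poi <- enc$total_cost * is_prev
  enc$w_n_tov <- as.numeric(is_out)
  enc$w_n_pov <- as.numeric(is_prev)
  enc$w_n_ibd <- as.numeric(enc$bed_days)
  enc$w_n_ms <- as.numeric(is_child &
    enc$service_type %in% c("outpatient_curative", "inpatient"))
  enc$w_n_phs <- as.numeric(is_child & enc$service_type == "public_health")
  enc$w_n_ms_all <- as.numeric(enc$service_type %in%
    c("outpatient_curative", "inpatient"))
  enc$w_n_phs_all <- as.numeric(enc$service_type == "public_health")

  sum_cols <- function(df) {
    dplyr::summarise(df,
      e_toi = sum(.data$w_e_toi), e_poi = sum(.data$w_e_poi),
      n_tov = sum(.data$w_n_tov), n_pov = sum(.data$w_n_pov),
      n_ibd = sum(.data$w_n_ibd),
      n_ms = sum(.data$w_n_ms), n_phs = sum(.data$w_n_phs),
      n_ms_all = sum(.data$w_n_ms_all), n_phs_all = sum(.data$w_n_phs_all),
      n_records = dplyr::n(), .groups = "drop"
    )
  }
  by_stratum <- sum_cols(dplyr::group_by(enc, .data$provider_type))
  pooled <- sum_cols(enc)

  shares <- enc |>
    dplyr::group_by(.data$provider_type, .data$service_type) |>
    dplyr::summarise(
      child_cost = sum(.data$total_cost[.data$age_years <= target_age_max]),
      total_cost = sum(.data$total_cost),
      .groups = "drop"
    ) |>
    dplyr::mutate(share = ifelse(.data$total_cost > 0,
                                 .data$child_cost / .data$total_cost, NA_real_))

  structure(
    list(by_stratum = by_stratum, pooled = pooled,
         children_cost_share = shares, target_age_max = target_age_max),
    class = "survey_tallies"
  )
}

join_provider_type <- function(encounters, institutions) {
  map <- institutions[c("institution_id", "provider_type")]
  enc <- dplyr::left_join(encounters, map, by = "institution_id")
  if (anyNA(enc$provider_type)) {
    bad <- unique(enc$institution_id[is.na(enc$provider_type)])
    stop("encounter(s) reference unknown institution(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  enc
}

#' Curative share of outpatient income (alpha_i = 1 - E_POI/E_TOI)
#'
#' @param tallies A `survey_tallies` object (the pooled tallies are used).
#' @return Proportion in `[0, 1]`.
#' @export
curative_outpatient_fraction <- function(tallies) {
  p <- tallies$pooled
  if (p$e_toi <= 0) stop("division error: total outpatient income E_TOI is zero", call. = FALSE)
  1 - p$e_poi / p$e_toi
}

#' Curative share of the basic subsidy (alpha_s = N_MS/(N_MS + N_PHS))
#'
#' Equivalent-person allocation: each service contact counts as one person
#' equivalent, so the subsidy follows the headcount split between medical
#' services and public-health services.
#'
#' @inheritParams curative_outpatient_fraction
#' @return Proportion in `[0, 1]`.
#' @export
subsidy_curative_fraction <- function(tallies) {
  p <- tallies$pooled
  if (p$n_ms + p$n_phs <= 0) {
    stop("division error: no medical-service or public-health contacts", call. = FALSE)
  }
  p$n_ms / (p$n_ms + p$n_phs)
}

#' Curative share of outpatient visits (upsilon = 1 - N_POV/N_TOV)
#'
#' @inheritParams curative_outpatient_fraction
#' @return Proportion in `[0, 1]`.
#' @export
curative_visit_fraction <- function(tallies) {
  p <- tallies$pooled
  if (p$n_tov <= 0) stop("division error: total outpatient visits N_TOV is zero", call. = FALSE)
  1 - p$n_pov / p$n_tov
}

#' Inpatient share of curative workload (beta)
#'
#' `beta = N_IBD / (N_IBD + N_IOV * kappa)`: bed days against
#' outpatient-visit bed-day equivalents, with `kappa` (default 0.1) the
#' number of bed-day equivalents one curative outpatient visit represents.
#'
#' @param n_ibd Inpatient bed days.
#' @param n_iov Curative outpatient visits.
#' @param kappa Positive equivalence constant (default 0.1).
#' @return Proportion in `[0, 1]`; increasing in `n_ibd`, decreasing in
#'   `n_iov`.
#' @export
inpatient_workload_share <- function(n_ibd, n_iov, kappa = 0.1) {
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  denom <- n_ibd + n_iov * kappa
  if (any(denom <= 0)) stop("division error: zero workload denominator", call. = FALSE)
  n_ibd / denom
}

#' Estimate the full coefficient set
#'
#' Composes the four coefficient formulas, per provider-type stratum with a
#' pooled fallback wherever a stratum's denominator is empty. The curative
#' outpatient visit count `N_IOV = N_OV * upsilon` uses the provincial visit
#' count; `N_IBD` in `beta` likewise uses the provincial bed-day count by
#' default (`n_ibd_source = "provincial"`), falling back to the survey tally
#' when requested or when the provincial count is absent.
#'
#' @param tallies A `survey_tallies` object from [tally_survey()].
#' @param provincial A [provincial_aggregates()] object.
#' @param kappa Outpatient-visit bed-day equivalence constant (default 0.1).
#' @param n_ibd_source `"provincial"` (default) or `"survey"`.
#' @return Object of class `coefficient_set`: `by_stratum` tibble
#'   (`provider_type`, `alpha_i`, `alpha_s`, `upsilon`, `beta`, `n_iov`,
#'   per-coefficient fallback flags), `pooled` one-row tibble, `kappa`,
#'   `children_cost_share`, provenance fields.
#' @export
estimate_coefficients <- function(tallies, provincial, kappa = 0.1,
                                  n_ibd_source = c("provincial", "survey")) {
  n_ibd_source <- match.arg(n_ibd_source)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  prov <- provincial$strata
  if (sum(prov$outpatient_visits) <= 0) {
    stop("provincial outpatient visit count N_OV must be positive", call. = FALSE)
  }
  p <- tallies$pooled
  pooled_alpha_i <- curative_outpatient_fraction(tallies)
  # alpha_s measures equivalent persons on the target (child) population; if
  # the survey holds no child contacts at all, fall back to all-ages counts
  pooled_alpha_s <- if (p$n_ms + p$n_phs > 0) {
    subsidy_curative_fraction(tallies)
  } else if (!is.null(p$n_ms_all) && p$n_ms_all + p$n_phs_all > 0) {
    warning("no child service contacts in the survey; ",
            "alpha_s falls back to all-ages counts")
    p$n_ms_all / (p$n_ms_all + p$n_phs_all)
  } else {
    stop("division error: no service contacts to estimate alpha_s", call. = FALSE)
  }
  pooled_upsilon <- curative_visit_fraction(tallies)
  pooled_n_iov <- sum(prov$outpatient_visits) * pooled_upsilon
  pooled_ibd <- if (n_ibd_source == "provincial") sum(prov$inpatient_bed_days) else p$n_ibd
  pooled_beta <- inpatient_workload_share(pooled_ibd, pooled_n_iov, kappa)

  strata <- union(prov$provider_type, tallies$by_stratum$provider_type)
  t_s <- tallies$by_stratum[match(strata, tallies$by_stratum$provider_type), ]
  p_s <- prov[match(strata, prov$provider_type), ]
  num0 <- function(x) ifelse(is.na(x), 0, x)

  e_toi <- num0(t_s$e_toi); e_poi <- num0(t_s$e_poi)
  n_ms <- num0(t_s$n_ms); n_phs <- num0(t_s$n_phs)
  n_tov <- num0(t_s$n_tov); n_pov <- num0(t_s$n_pov)
  n_ov <- num0(p_s$outpatient_visits)
  ibd <- if (n_ibd_source == "provincial") num0(p_s$inpatient_bed_days) else num0(t_s$n_ibd)

  alpha_i <- ifelse(e_toi > 0, 1 - e_poi / e_toi, pooled_alpha_i)
  alpha_s <- ifelse(n_ms + n_phs > 0, n_ms / (n_ms + n_phs), pooled_alpha_s)
  upsilon <- ifelse(n_tov > 0, 1 - n_pov / n_tov, pooled_upsilon)
  n_iov <- n_ov * upsilon
  denom <- ibd + n_iov * kappa
  beta <- ifelse(denom > 0, ibd / denom, pooled_beta)

  by_stratum <- tibble::tibble(
    provider_type = strata,
    alpha_i = alpha_i, alpha_s = alpha_s, upsilon = upsilon,
    beta = beta, n_iov = n_iov,
    fallback_alpha_i = e_toi <= 0,
    fallback_alpha_s = n_ms + n_phs <= 0,
    fallback_upsilon = n_tov <= 0,
    fallback_beta = denom <= 0
  )
  structure(
    list(
      by_stratum = by_stratum,
      pooled = tibble::tibble(
        alpha_i = pooled_alpha_i, alpha_s = pooled_alpha_s,
        upsilon = pooled_upsilon, beta = pooled_beta, n_iov = pooled_n_iov
      ),
      kappa = kappa,
      n_ibd_source = n_ibd_source,
      children_cost_share = tallies$children_cost_share,
      target_age_max = tallies$target_age_max,
      provenance = list(
        survey_records = p$n_records,
        e_poi = p$e_poi, e_toi = p$e_toi, n_ms = p$n_ms, n_phs = p$n_phs,
        n_pov = p$n_pov, n_tov = p$n_tov, survey_n_ibd = p$n_ibd,
        provincial_n_ov = sum(prov$outpatient_visits),
        provincial_n_ibd = sum(prov$inpatient_bed_days)
      )
    ),
    class = "coefficient_set"
  )
}

#' Serialize / read a coefficient set as a YAML document
#' @param coefficients A `coefficient_set`.
#' @param path YAML file path.
#' @export
write_coefficients <- function(coefficients, path) {
  doc <- list(
    kappa = coefficients$kappa,
    n_ibd_source = coefficients$n_ibd_source,
    target_age_max = coefficients$target_age_max,
    pooled = as.list(coefficients$pooled),
    provenance = coefficients$provenance,
    by_stratum = lapply(seq_len(nrow(coefficients$by_stratum)), function(i) {
      as.list(coefficients$by_stratum[i, ])
    }),
    children_cost_share = lapply(seq_len(nrow(coefficients$children_cost_share)),
      function(i) as.list(coefficients$children_cost_share[i, ]))
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  doc <- yaml::read_yaml(path)
  structure(
    list(
      by_stratum = dplyr::bind_rows(lapply(doc$by_stratum, tibble::as_tibble)),
      pooled = tibble::as_tibble(doc$pooled),
      kappa = doc$kappa,
      n_ibd_source = doc$n_ibd_source,
      children_cost_share = dplyr::bind_rows(lapply(doc$children_cost_share, tibble::as_tibble)),
      target_age_max = doc$target_age_max,
      provenance = doc$provenance
    ),
    class = "coefficient_set"
  )
}
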