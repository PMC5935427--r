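# Fixtures are generated in code at test time; no data files are shipped.

# small synthetic province for unit tests (~2.5k encounters, 21 institutions)
tiny_config <- function(seed = 101L, ...) {
  args <- utils::modifyList(tiny_defaults(), list(seed = seed, ...))
  do.call(generator_config, args)
}

tiny_defaults <- function() {
  list(
    n_cities = 2,
    institutions_per_city = c(
      general_hospital = 2, specialized_hospital = 1, township_hospital = 2,
      community_health_center = 1, maternal_child_center = 1,
      outpatient_service_institution = 1, village_or_individual_clinic = 1,
      public_health_institution = 1
    ),
    n_provincial_hospitals = 1,
    encounters_per_institution = c(
      provincial_hospital = 400, general_hospital = 300,
      specialized_hospital = 120, tcm_hospital = 120,
      maternal_child_center = 120, outpatient_service_institution = 80,
      township_hospital = 80, community_health_center = 80,
      village_or_individual_clinic = 40, public_health_institution = 60
    )
  )
}

tiny_dataset <- local({
  cache <- new.env()
  function(seed = 101L) {
    key <- paste0("ds", seed)
    if (is.null(cache[[key]])) cache[[key]] <- generate_dataset(tiny_config(seed))
    cache[[key]]
  }
})

# a one-encounter hand-built dataset: outpatient curative, age 3, chapter
# J (respiratory), cost 100, fully out-of-pocket, no subsidies
manual_dataset <- function() {
  enc <- tibble::tibble(
    institution_id = "I001", age_years = 3L, sex = "female",
    icd10_code = "J18.9", service_type = "outpatient_curative",
    bed_days = 0L, total_cost = 100,
    pay_social_insurance = 0, pay_commercial_insurance = 0, pay_donation = 0,
    pay_government_program = 0, pay_out_of_pocket = 100
  )
  inst <- tibble::tibble(
    institution_id = "I001", provider_type = "general_hospital", city = "city1",
    outpatient_income = 100, preventive_outpatient_income = 0,
    inpatient_income = 0, basic_subsidy = 0, outpatient_project_subsidy = 0,
    inpatient_project_subsidy = 0, superior_institution_subsidy = 0,
    science_education_income = 0, other_income = 0,
    assistant_service_cost = 0, medicine_cost = 0, management_cost = 0,
    capital_expenditure = 0,
    projects = list(tibble::tibble(project_id = character(),
                                   income = numeric(), expense = numeric()))
  )
  prov <- provincial_aggregates(tibble::tibble(
    provider_type = "general_hospital", outpatient_income = 100,
    inpatient_income = 0, outpatient_visits = 1, inpatient_bed_days = 0,
    basic_subsidy = 0, outpatient_project_subsidy = 0,
    inpatient_project_subsidy = 0
  ), year = 2014)
  structure(
    list(institutions = inst, encounters = enc, provincial = prov,
         truth = NULL, config = generator_config(seed = 1L),
         sampling_plan = NULL),
    class = "synthetic_dataset"
  )
}

# hand-constructed tallies for the coefficient formula checks
fake_tallies <- function(e_poi = 0, e_toi = 1, n_ms = 1, n_phs = 0,
                         n_tov = 1, n_pov = 0, n_ibd = 0) {
  structure(
    list(pooled = tibble::tibble(
      e_poi = e_poi, e_toi = e_toi, n_ms = n_ms, n_phs = n_phs,
      n_tov = n_tov, n_pov = n_pov, n_ibd = n_ibd, n_records = 1
    )),
    class = "survey_tallies"
  )
}

# cube carrying the printed spending-by-provider table (US$ million; rate 1
# and unit 1 so the renderer reproduces the printed numbers)
printed_provider_cube <- function() {
  cells <- tibble::tribble(
    ~provider_type, ~outpatient, ~inpatient,
    "township_hospital", 1.70, 0.48,
    "outpatient_service_institution", 3.40, 0,
    "maternal_child_center", 0.31, 4.72,
    "general_hospital", 29.38, 694.09,
    "specialized_hospital", 0.07, 0.03,
    "tcm_hospital", 1.37, 2.02
  )
  long <- dplyr::bind_rows(
    tibble::tibble(provider_type = cells$provider_type,
                   fn = "curative_outpatient", amount_cny = cells$outpatient),
    tibble::tibble(provider_type = cells$provider_type,
                   fn = "curative_inpatient", amount_cny = cells$inpatient)
  )
  long$financing <- "household"
  long$disease_class <- "unclassified"
  long$age_bin <- "0-1"
  accounts_cube(long, currency = "USD_million", year = 2014,
                scope = "children_0_14")
}

# printed funding-schemes components (US$ million)
printed_financing_sources <- function() {
  tibble::tibble(
    source = c("basic_subsidy", "project_subsidy",
               "superior_institution_subsidy", "medical_income",
               "science_education_income", "others"),
    amount_cny = c(19.32, 7.73, 0.13, 591.40, 0.02, 7.73)
  )
}

max_rel_cell_err <- function(cube_a, cube_b) {
  j <- dplyr::full_join(
    tibble::as_tibble(cube_a), tibble::as_tibble(cube_b),
    by = c("provider_type", "fn", "financing", "disease_class", "age_bin"),
    suffix = c("_a", "_b")
  )
  j$amount_cny_a[is.na(j$amount_cny_a)] <- 0
  j$amount_cny_b[is.na(j$amount_cny_b)] <- 0
  max(abs(j$amount_cny_a - j$amount_cny_b) / pmax(abs(j$amount_cny_b), 1e-6))
}
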