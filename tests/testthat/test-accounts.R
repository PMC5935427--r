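test_that("curative income and subsidy splits match hand evaluation", {
  prov <- provincial_aggregates(tibble::tibble(
    provider_type = c("general_hospital", "township_hospital"),
    outpatient_income = c(1000, 500), inpatient_income = c(2000, 100),
    outpatient_visits = c(10, 5), inpatient_bed_days = c(20, 1),
    basic_subsidy = c(100, 50), outpatient_project_subsidy = c(10, 5),
    inpatient_project_subsidy = c(20, 2)
  ))
  expect_equal(curative_outpatient_income(prov, 0.8)$e_oci, c(800, 400))
  expect_equal(curative_outpatient_income(prov, 1)$e_oci, c(1000, 500))
  expect_equal(curative_outpatient_income(prov, 0)$e_oci, c(0, 0))
  expect_error(curative_outpatient_income(prov, 1.2), "\\[0, 1\\]")

  s <- split_basic_subsidy(1000, 0.75, 0.5)
  expect_equal(s$e_bcs, 750)
  expect_equal(s$e_obs, 375)
  expect_equal(s$e_ibs, 375)
  expect_equal(split_basic_subsidy(1000, 0.4, 0)$e_obs, 400) # beta=0: all outpatient
  expect_equal(unlist(split_basic_subsidy(1000, 0, 0.3)), c(e_bcs = 0, e_obs = 0, e_ibs = 0))
  s2 <- split_basic_subsidy(c(100, 200), c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(s2$e_obs + s2$e_ibs, s2$e_bcs)
})

test_that("prevention expenditure takes the larger of income and expense", {
  expect_equal(prevention_expenditure(tibble::tibble(income = 80, expense = 100)), 100)
  expect_equal(prevention_expenditure(tibble::tibble(income = 100, expense = 100)), 100)
  expect_equal(prevention_expenditure(
    tibble::tibble(income = c(80, 120), expense = c(100, 90))), 220)
  expect_equal(prevention_expenditure(
    tibble::tibble(income = c(80, 120), expense = c(100, 90)),
    rule = "expense_always"), 190)
  expect_equal(prevention_expenditure(NULL), 0)
  expect_error(prevention_expenditure(tibble::tibble(income = -1, expense = 2)),
               "non-negative")
})

test_that("financing assignment follows the scheme rule and conserves money", {
  b <- assign_financing("basic_subsidy", 500)
  expect_equal(unlist(b), c(government = 500, social = 0, household = 0))
  e <- assign_financing("encounter_payment", 100,
                        payer_split = c(social_insurance = 60, out_of_pocket = 40))
  expect_equal(unlist(e), c(government = 0, social = 60, household = 40))
  g <- assign_financing("encounter_payment", 10,
                        payer_split = c(government_program = 4, donation = 3,
                                        commercial_insurance = 3))
  expect_equal(unlist(g), c(government = 4, social = 6, household = 0))
  z <- assign_financing("project_subsidy", 0)
  expect_equal(sum(unlist(z)), 0)
  expect_error(assign_financing("encounter_payment", 100,
                                payer_split = c(out_of_pocket = 90)), "sum")
})

test_that("curative account totals satisfy the accounting identities", {
  ds <- tiny_dataset()
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial)
  ca <- curative_totals(ds$provincial, cf)
  expect_equal(ca$e_ocs, ca$e_oci + ca$e_ops + ca$e_obs, tolerance = 1e-9)
  expect_equal(ca$e_ics, ca$e_ici + ca$e_ips + ca$e_ibs, tolerance = 1e-9)
  expect_equal(ca$e_obs + ca$e_ibs, ca$e_bcs, tolerance = 1e-9)
  # zero aggregates give an all-zero account
  zero <- ds$provincial
  zero$strata[setdiff(names(zero$strata), c("provider_type", "outpatient_visits"))] <- 0
  ca0 <- curative_totals(zero, cf)
  expect_equal(sum(ca0$e_ocs) + sum(ca0$e_ics), 0)
})

test_that("the top-down cube reproduces the census truth cell-wise at 100% sampling", {
  ds <- tiny_dataset()
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial, kappa = ds$config$kappa)
  cube <- compute_che(ds$provincial, ds$encounters, ds$institutions, cf)
  expect_lt(max_rel_cell_err(cube, ds$truth), 1e-9)
  kids <- restrict_to_children(cube)
  truth_kids <- restrict_to_children(ds$truth)
  expect_lt(max_rel_cell_err(kids, truth_kids), 1e-9)
})

test_that("the top-down method is linear in the provincial money aggregates", {
  ds <- tiny_dataset()
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial)
  cube1 <- compute_che(ds$provincial, ds$encounters, ds$institutions, cf)
  doubled <- ds$provincial
  for (col in c("outpatient_income", "inpatient_income", "basic_subsidy",
                "outpatient_project_subsidy", "inpatient_project_subsidy")) {
    doubled$strata[[col]] <- 2 * doubled$strata[[col]]
  }
  cube2 <- compute_che(doubled, ds$encounters, ds$institutions, cf)
  j <- dplyr::inner_join(tibble::as_tibble(cube1), tibble::as_tibble(cube2),
                         by = c("provider_type", "fn", "financing",
                                "disease_class", "age_bin"))
  expect_equal(nrow(j), nrow(cube1))
  expect_equal(j$amount_cny.y, 2 * j$amount_cny.x, tolerance = 1e-9)
})

test_that("cube marginals are additive and financing decomposition conserves money", {
  ds <- tiny_dataset()
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial)
  cube <- compute_che(ds$provincial, ds$encounters, ds$institutions, cf)
  total <- cube_total(cube)
  for (dim in c("provider_type", "fn", "financing", "disease_class", "age_bin")) {
    expect_equal(sum(cube_margin(cube, dim)$amount_cny), total,
                 tolerance = 1e-6 * total, label = dim)
  }
  fin <- cube_margin(cube, "financing")
  expect_setequal(fin$financing, c("government", "social", "household"))
  expect_true(all(cube$amount_cny >= 0))
})

test_that("a universe without children gives an empty children cube", {
  adult_ages <- c(rep(0, 15), rep(1, 86)) # all weight on ages 15+
  cfg <- tiny_config(seed = 5L, age_distribution = adult_ages)
  ds <- generate_dataset(cfg)
  expect_warning(
    cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                                ds$provincial),
    "alpha_s")
  cube <- compute_che(ds$provincial, ds$encounters, ds$institutions, cf)
  kids <- restrict_to_children(cube)
  expect_equal(cube_total(kids), 0)
})

test_that("a universe of only children is untouched by the children restriction", {
  child_ages <- c(rep(1, 15), rep(0, 86))
  cfg <- tiny_config(seed = 6L, age_distribution = child_ages)
  ds <- generate_dataset(cfg)
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial)
  cube <- compute_che(ds$provincial, ds$encounters, ds$institutions, cf)
  kids <- restrict_to_children(cube)
  expect_equal(cube_total(kids), cube_total(cube), tolerance = 1e-9)
  expect_equal(nrow(kids), nrow(cube))
})
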