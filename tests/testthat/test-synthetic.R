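test_that("generation is deterministic for a fixed seed", {
  a <- generate_dataset(tiny_config(seed = 7L))
  b <- generate_dataset(tiny_config(seed = 7L))
  expect_identical(a$encounters, b$encounters)
  expect_identical(a$institutions[setdiff(names(a$institutions), "projects")],
                   b$institutions[setdiff(names(b$institutions), "projects")])
  expect_equal(a$provincial$strata, b$provincial$strata)
  expect_equal(as.data.frame(a$truth), as.data.frame(b$truth))
  c <- generate_dataset(tiny_config(seed = 8L))
  expect_false(identical(a$encounters, c$encounters))
})

test_that("a zero encounter rate yields an empty universe with zero income", {
  cfg <- tiny_config(seed = 3L, encounters_per_institution = 0)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$encounters), 0)
  expect_equal(sum(ds$provincial$strata$outpatient_income), 0)
  expect_equal(sum(ds$provincial$strata$inpatient_income), 0)
  # income-linked subsidies and overheads vanish with the encounters; only
  # government prevention-project money (independent of fee income) remains
  proj <- sum(vapply(ds$institutions$projects,
                     function(p) sum(pmax(p$income, p$expense)), numeric(1)))
  expect_equal(cube_total(ds$truth), proj, tolerance = 1e-9)
  expect_equal(sum(ds$institutions$basic_subsidy), 0)
})

test_that("invalid generator configs fail naming the offending field", {
  expect_error(generator_config(preventive_visit_share = 1.2),
               "preventive_visit_share")
  expect_error(generator_config(n_cities = 0), "n_cities")
  expect_error(generator_config(kappa = -1), "kappa")
  expect_error(generator_config(age_distribution = rep(1, 5)), "age_distribution")
  expect_error(generator_config(
    payer_split_distribution = c(out_of_pocket = 1)), "payer_split_distribution")
  expect_error(generator_config(
    disease_distribution = c(Narnia = 1)), "disease_distribution")
})

test_that("the census conserves money: province = institutions = encounters", {
  ds <- tiny_dataset()
  enc_out <- sum(ds$encounters$total_cost[
    ds$encounters$service_type %in% c("outpatient_curative", "outpatient_preventive")])
  enc_in <- sum(ds$encounters$total_cost[ds$encounters$service_type == "inpatient"])
  expect_equal(sum(ds$institutions$outpatient_income), enc_out, tolerance = 1e-9)
  expect_equal(sum(ds$institutions$inpatient_income), enc_in, tolerance = 1e-9)
  expect_equal(sum(ds$provincial$strata$outpatient_income), enc_out, tolerance = 1e-9)
  expect_equal(sum(ds$provincial$strata$inpatient_income), enc_in, tolerance = 1e-9)
  expect_equal(sum(ds$provincial$strata$outpatient_visits),
               sum(ds$encounters$service_type %in%
                     c("outpatient_curative", "outpatient_preventive")))
  expect_equal(sum(ds$provincial$strata$inpatient_bed_days),
               sum(ds$encounters$bed_days))
})

test_that("every generated encounter is a valid record", {
  ds <- tiny_dataset()
  enc <- ds$encounters
  expect_true(all(enc$age_years >= 0 & enc$age_years <= 100))
  expect_true(all(enc$total_cost >= 0))
  expect_true(all(enc$bed_days == 0 | enc$service_type == "inpatient"))
  chapters <- icd10_chapter(enc$icd10_code) # errors on any invalid code
  expect_false(any(chapters == "unclassified"))
  pay <- rowSums(as.matrix(enc[paste0("pay_", che_payer_categories)]))
  expect_true(all(abs(pay - enc$total_cost) <= 1e-6 * pmax(enc$total_cost, 1)))
  ph <- enc$service_type == "public_health"
  expect_true(all(enc$total_cost[ph] == 0))
})

test_that("empirical chapter frequencies match the configured weights", {
  cfg <- generator_config(seed = 33L)
  ds <- generate_dataset(cfg)
  cur <- ds$encounters[ds$encounters$service_type %in%
                         c("outpatient_curative", "inpatient"), ]
  chap <- icd10_chapter(cur$icd10_code)
  n <- nrow(cur)
  w <- cfg$disease_distribution
  for (ch in names(w)) {
    p_hat <- mean(chap == ch)
    se <- sqrt(w[[ch]] * (1 - w[[ch]]) / n)
    expect_lt(abs(p_hat - w[[ch]]), 3 * se + 1e-9)
  }
})

test_that("drawing the full frame returns the census; draws are seed-stable", {
  ds <- tiny_dataset()
  all_in <- draw_survey(ds, sampling_plan(institution_fraction = 1), seed = 1)
  expect_identical(all_in$institutions$institution_id,
                   ds$institutions$institution_id)
  expect_identical(all_in$encounters, ds$encounters)

  two_a <- draw_survey(ds, sampling_plan(n_cities = 1), seed = 9)
  two_b <- draw_survey(ds, sampling_plan(n_cities = 1), seed = 9)
  expect_identical(two_a$institutions$institution_id,
                   two_b$institutions$institution_id)
  expect_error(draw_survey(ds, sampling_plan(n_cities = 40), seed = 1),
               "sampling error")
})

test_that("a half sample holds about half the census money", {
  ds <- generate_dataset(generator_config(seed = 12L))
  sv <- draw_survey(ds, sampling_plan(institution_fraction = 0.5), seed = 21)
  frac <- sum(sv$institutions$outpatient_income + sv$institutions$inpatient_income) /
    sum(ds$institutions$outpatient_income + ds$institutions$inpatient_income)
  # institution sizes vary a lot, so allow a broad band around one half
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.75)
  expect_true(all(sv$institutions$institution_id %in% ds$institutions$institution_id))
})

test_that("truth tabulation: empty and single-record cases", {
  # a truly empty universe (no institutions generate prevention projects
  # either) gives the all-zero cube
  empty <- generate_dataset(tiny_config(
    seed = 4L, encounters_per_institution = 0,
    institutions_per_city = c(general_hospital = 2),
    n_provincial_hospitals = 0))
  expect_equal(cube_total(empty$truth), 0)

  one <- manual_dataset()
  cube <- tabulate_truth(one)
  expect_equal(nrow(cube), 1)
  expect_equal(cube$amount_cny, 100)
  expect_equal(cube$financing, "household")
  expect_equal(cube$fn, "curative_outpatient")
  expect_equal(cube$disease_class, "Respiratory system diseases")
  expect_equal(cube$age_bin, "3-4")

  sv <- draw_survey(tiny_dataset(), sampling_plan(institution_fraction = 0.5), 1)
  expect_error(tabulate_truth(sv), "census")
})

test_that("truth cube total equals generated money: costs plus subsidies", {
  ds <- tiny_dataset()
  inst <- ds$institutions
  expected <- sum(ds$encounters$total_cost) +
    sum(inst$basic_subsidy) +
    sum(inst$outpatient_project_subsidy) + sum(inst$inpatient_project_subsidy) +
    sum(vapply(inst$projects, function(p) sum(pmax(p$income, p$expense)), numeric(1))) +
    sum(inst$assistant_service_cost) + sum(inst$medicine_cost) +
    sum(inst$management_cost)
  expect_equal(cube_total(ds$truth), expected, tolerance = 1e-9)
  # capital expenditure is generated but never enters CHE
  expect_gt(sum(inst$capital_expenditure), 0)
})
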