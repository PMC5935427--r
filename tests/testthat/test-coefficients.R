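test_that("coefficient formulas reproduce hand-computed values and boundaries", {
  # alpha_i = 1 - E_POI/E_TOI
  expect_equal(curative_outpatient_fraction(fake_tallies(e_poi = 200, e_toi = 1000)), 0.8)
  expect_equal(curative_outpatient_fraction(fake_tallies(e_poi = 0, e_toi = 500)), 1)
  expect_equal(curative_outpatient_fraction(fake_tallies(e_poi = 500, e_toi = 500)), 0)
  expect_error(curative_outpatient_fraction(fake_tallies(e_toi = 0)), "division")
  # alpha_s = N_MS/(N_MS + N_PHS)
  expect_equal(subsidy_curative_fraction(fake_tallies(n_ms = 300, n_phs = 100)), 0.75)
  expect_equal(subsidy_curative_fraction(fake_tallies(n_ms = 5, n_phs = 5)), 0.5)
  expect_equal(subsidy_curative_fraction(fake_tallies(n_ms = 7, n_phs = 0)), 1)
  expect_error(subsidy_curative_fraction(fake_tallies(n_ms = 0, n_phs = 0)), "division")
  # upsilon = 1 - N_POV/N_TOV
  expect_equal(curative_visit_fraction(fake_tallies(n_pov = 150, n_tov = 600)), 0.75)
  expect_equal(curative_visit_fraction(fake_tallies(n_pov = 0, n_tov = 10)), 1)
  expect_equal(curative_visit_fraction(fake_tallies(n_pov = 10, n_tov = 10)), 0)
  expect_error(curative_visit_fraction(fake_tallies(n_tov = 0)), "division")
  # beta = N_IBD/(N_IBD + N_IOV * kappa)
  expect_equal(inpatient_workload_share(1000, 10000, 0.1), 0.5)
  expect_equal(inpatient_workload_share(500, 0, 0.1), 1)
  expect_equal(inpatient_workload_share(0, 100, 0.1), 0)
  expect_error(inpatient_workload_share(0, 0, 0.1), "division")
  expect_error(inpatient_workload_share(10, 10, 0), "kappa")
})

test_that("beta is monotone: increasing in bed days, decreasing in visits", {
  for (ibd in c(10, 100, 1000)) {
    b <- vapply(c(100, 1000, 10000), function(iov) {
      inpatient_workload_share(ibd, iov, 0.1)
    }, numeric(1))
    expect_true(all(diff(b) < 0))
    expect_true(all(b >= 0 & b <= 1))
  }
  b2 <- vapply(c(10, 100, 1000), function(ibd) {
    inpatient_workload_share(ibd, 1000, 0.1)
  }, numeric(1))
  expect_true(all(diff(b2) > 0))
})

test_that("survey tallies equal a brute-force enumeration of the record list", {
  ds <- tiny_dataset()
  tl <- tally_survey(ds$encounters, ds$institutions)
  enc <- as.data.frame(ds$encounters)
  type_of <- setNames(ds$institutions$provider_type, ds$institutions$institution_id)
  # independent pass: plain loops over the record list
  acc <- list(e_toi = 0, e_poi = 0, n_tov = 0, n_pov = 0, n_ibd = 0,
              n_ms = 0, n_phs = 0)
  for (i in seq_len(nrow(enc))) {
    st <- enc$service_type[i]
    if (st %in% c("outpatient_curative", "outpatient_preventive")) {
      acc$e_toi <- acc$e_toi + enc$total_cost[i]
      acc$n_tov <- acc$n_tov + 1
    }
    if (st == "outpatient_preventive") {
      acc$e_poi <- acc$e_poi + enc$total_cost[i]
      acc$n_pov <- acc$n_pov + 1
    }
    acc$n_ibd <- acc$n_ibd + enc$bed_days[i]
    if (enc$age_years[i] <= 14) {
      if (st %in% c("outpatient_curative", "inpatient")) acc$n_ms <- acc$n_ms + 1
      if (st == "public_health") acc$n_phs <- acc$n_phs + 1
    }
  }
  for (nm in names(acc)) {
    expect_equal(tl$pooled[[nm]], acc[[nm]], tolerance = 1e-12, label = nm)
  }
  # stratum rows sum to the pooled row
  expect_equal(sum(tl$by_stratum$e_toi), tl$pooled$e_toi, tolerance = 1e-9)
  expect_equal(sum(tl$by_stratum$n_ms), tl$pooled$n_ms)
  expect_error(tally_survey(ds$encounters[0, ], ds$institutions), "no survey records")
})

test_that("the child filter is inclusive of the boundary age", {
  inst <- tibble::tibble(institution_id = "A", provider_type = "general_hospital")
  enc <- tibble::tibble(
    institution_id = "A", age_years = c(2L, 14L, 15L), sex = "female",
    icd10_code = "J18", service_type = "outpatient_curative", bed_days = 0L,
    total_cost = 10, pay_social_insurance = 0, pay_commercial_insurance = 0,
    pay_donation = 0, pay_government_program = 0, pay_out_of_pocket = 10
  )
  tl <- tally_survey(enc, inst, target_age_max = 14)
  expect_equal(tl$pooled$n_ms, 2) # ages 2 and 14 count as children; 15 does not
})

test_that("estimated coefficients recover generator ground truth on the census", {
  ds <- tiny_dataset()
  tl <- tally_survey(ds$encounters, ds$institutions)
  cf <- estimate_coefficients(tl, ds$provincial, kappa = ds$config$kappa)
  # preventive share 25% configured => upsilon ~ 0.75 within 3 binomial SE
  n <- tl$pooled$n_tov
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(cf$pooled$upsilon - 0.75), 3 * se)
  expect_true(all(cf$by_stratum$alpha_i >= 0 & cf$by_stratum$alpha_i <= 1))
  expect_true(all(cf$by_stratum$beta >= 0 & cf$by_stratum$beta <= 1))
  # determinism: same tallies twice -> identical sets
  cf2 <- estimate_coefficients(tl, ds$provincial, kappa = ds$config$kappa)
  expect_identical(cf, cf2)
})

test_that("an all-curative survey gives alpha_i = upsilon = 1 and N_IOV = N_OV", {
  cfg <- tiny_config(seed = 7L, preventive_visit_share = 0,
                     service_mix = c(outpatient = 0.9, inpatient = 0.1,
                                     public_health = 0))
  ds <- generate_dataset(cfg)
  tl <- tally_survey(ds$encounters, ds$institutions)
  cf <- estimate_coefficients(tl, ds$provincial)
  expect_equal(cf$pooled$alpha_i, 1)
  expect_equal(cf$pooled$upsilon, 1)
  expect_equal(cf$pooled$n_iov, sum(ds$provincial$strata$outpatient_visits))
})

test_that("survey estimates converge to census values as the sample grows", {
  ds <- tiny_dataset()
  census_cf <- estimate_coefficients(
    tally_survey(ds$encounters, ds$institutions), ds$provincial)
  est <- function(fraction) {
    sv <- draw_survey(ds, sampling_plan(institution_fraction = fraction), seed = 5)
    estimate_coefficients(tally_survey(sv$encounters, sv$institutions),
                          ds$provincial)
  }
  # 100% sample reproduces the census coefficients exactly
  full <- est(1)
  expect_equal(full$pooled, census_cf$pooled, tolerance = 1e-12)
  # smaller samples land within sampling error and tighten as n grows
  err <- vapply(c(0.1, 0.5), function(f) {
    abs(est(f)$pooled$upsilon - census_cf$pooled$upsilon)
  }, numeric(1))
  expect_lt(err[2], 0.05)
  expect_lt(err[1], 0.15)
})

test_that("coefficient sets serialize to YAML and back", {
  ds <- tiny_dataset()
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_coefficients(cf, path)
  back <- read_coefficients(path)
  expect_equal(back$pooled, cf$pooled, tolerance = 1e-9)
  expect_equal(back$by_stratum$beta, cf$by_stratum$beta, tolerance = 1e-9)
  expect_equal(back$kappa, cf$kappa)
})
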