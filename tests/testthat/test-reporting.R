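test_that("currency conversion and half-up rounding reproduce printed figures", {
  # CNY 4,573 million at 6.20 CNY/USD = US$ 737.58 million = US$ 0.74 billion
  usd_million <- convert_currency(4573, 6.20)
  expect_equal(round_half_up(usd_million, 2), 737.58)
  expect_equal(round_half_up(usd_million / 1000, 2), 0.74)
  expect_equal(convert_currency(100, 1), 100)
  expect_equal(convert_currency(0, 3.5), 0)
  expect_error(convert_currency(10, 0), "positive")
  expect_error(convert_currency(10, -2), "positive")
  # commercial rounding, not round-half-to-even
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-0.005, 2), -0.01)
  expect_equal(round_half_up(1.25, 1), 1.3)
})

test_that("the provider table aggregates strata into the report categories", {
  tab <- render_provider_table(printed_provider_cube(), rate = 1, unit = 1,
                               digits = 2)
  hosp <- tab[tab$row == "Hospitals:", ]
  expect_equal(hosp$outpatient, 30.82)
  expect_equal(hosp$inpatient, 696.14)
  expect_equal(hosp$total, 726.96)
  mcc <- tab[tab$row == "Maternal and child care centers", ]
  expect_equal(mcc$total, 5.03) # 0.31 + 4.72
  gh <- tab[tab$row == "general hospital", ]
  expect_equal(gh$total, 723.47)
  # sub-rows sum to their parent
  sub <- tab[tab$level == "subrow", ]
  expect_equal(sum(sub$total), hosp$total, tolerance = 0.01 * nrow(sub))
  # an empty cube renders an all-zero table
  empty <- accounts_cube(tibble::as_tibble(printed_provider_cube())[0, ])
  tab0 <- render_provider_table(empty, rate = 1, unit = 1)
  expect_true(all(tab0$total == 0))
})

test_that("hospital dominance shares match the printed table arithmetic", {
  u <- attr(render_provider_table(printed_provider_cube(), rate = 1, unit = 1),
            "unrounded")
  grand <- sum(u$total[u$level == "row"])
  hosp <- u[u$row == "Hospitals:", ]
  expect_equal(round_half_up(100 * hosp$total / grand, 2), 98.56)
  gh <- u[u$row == "general hospital", ]
  expect_gte(gh$outpatient / hosp$outpatient, 0.95)
  expect_gte(gh$inpatient / hosp$inpatient, 0.99)
})

test_that("unmapped strata are a reporting error naming the stratum", {
  cells <- tibble::as_tibble(printed_provider_cube())
  cells$provider_type[1] <- "public_health_institution"
  map <- default_provider_report_map()
  map <- map[map$provider_type != "public_health_institution", ]
  expect_error(render_provider_table(accounts_cube(cells), provider_map = map),
               "public_health_institution")
})

test_that("the financing table composes sub-rows and the total as printed", {
  tab <- render_financing_table(printed_financing_sources(), rate = 1, unit = 1)
  amount <- function(rw) tab$amount[tab$row == rw]
  expect_equal(amount("Financial subsidy:"), 27.05) # 19.32 + 7.73
  expect_equal(amount("Total"), 626.33)
  # medical income is recoverable as the total minus every other component
  others <- amount("Financial subsidy:") +
    amount("Superior institution subsidy (only primary medical institutions)") +
    amount("Science and education income (only hospitals)") + amount("Others")
  expect_equal(amount("Total") - others, 591.40, tolerance = 1e-9)
  zero <- printed_financing_sources()
  zero$amount_cny <- 0
  expect_true(all(render_financing_table(zero)$amount == 0))
})

test_that("disease-age matrix normalizes every column to 100", {
  ds <- tiny_dataset()
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial)
  kids <- restrict_to_children(
    compute_che(ds$provincial, ds$encounters, ds$institutions, cf))
  suppressWarnings(tab <- render_disease_age_matrix(kids))
  u <- attr(tab, "unrounded")
  for (col in setdiff(names(u), "disease_class")) {
    s <- sum(u[[col]], na.rm = TRUE)
    if (s > 0) expect_lt(abs(s - 100), 0.05)
  }
  # degenerate cases: one disease -> 100; two equal diseases -> 50/50
  one <- accounts_cube(tibble::tibble(
    provider_type = "general_hospital", fn = "curative_outpatient",
    financing = "household", disease_class = "Tumor", age_bin = "3-4",
    amount_cny = 42))
  expect_warning(t1 <- render_disease_age_matrix(one), "zero spending")
  expect_equal(t1$`3-4`[t1$disease_class == "Tumor"], 100)
  two <- accounts_cube(tibble::tibble(
    provider_type = "general_hospital", fn = "curative_outpatient",
    financing = "household", disease_class = c("Tumor", "Blood diseases"),
    age_bin = "3-4", amount_cny = c(7, 7)))
  suppressWarnings(t2 <- render_disease_age_matrix(two))
  expect_equal(sort(t2$`3-4`), c(50, 50))
})

test_that("shares are invariant to the reporting currency", {
  ds <- tiny_dataset()
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial)
  kids <- restrict_to_children(
    compute_che(ds$provincial, ds$encounters, ds$institutions, cf))
  cny <- attr(render_provider_table(kids, rate = NULL), "unrounded")
  usd <- attr(render_provider_table(kids, rate = 6.20), "unrounded")
  expect_equal(cny$total / sum(cny$total[cny$level == "row"]),
               usd$total / sum(usd$total[usd$level == "row"]),
               tolerance = 1e-9)
  m_cny <- suppressWarnings(attr(render_disease_age_matrix(kids), "unrounded"))
  expect_equal(m_cny, suppressWarnings(attr(render_disease_age_matrix(kids), "unrounded")),
               tolerance = 1e-9)
})

test_that("the GBD-by-age series sums to 100 within every age bin", {
  ds <- tiny_dataset()
  cf <- estimate_coefficients(tally_survey(ds$encounters, ds$institutions),
                              ds$provincial)
  kids <- restrict_to_children(
    compute_che(ds$provincial, ds$encounters, ds$institutions, cf))
  g <- render_gbd_age_series(kids)
  sums <- tapply(g$percent, g$age_bin, sum)
  expect_true(all(abs(sums - 100) < 0.05))
  expect_true(all(g$gbd_group %in% c(
    "group_I_communicable_maternal_perinatal_nutritional",
    "group_II_noncommunicable", "group_III_injury", "unclassified")))
})

test_that("the pipeline is deterministic and fails with a stage-tagged error", {
  config <- list(
    generator = tiny_config(seed = 31L),
    plan = sampling_plan(institution_fraction = 0.5),
    survey_seed = 2L
  )
  r1 <- suppressWarnings(run_pipeline(config))
  r2 <- suppressWarnings(run_pipeline(config))
  expect_identical(r1$tables$provider, r2$tables$provider)
  expect_identical(r1$tables$disease_age, r2$tables$disease_age)
  expect_equal(as.data.frame(r1$cube_children), as.data.frame(r2$cube_children))
  expect_identical(r1$log, r2$log)
  # every coefficient in effect is logged
  expect_true(any(grepl("alpha_i=", r1$log)))
  expect_true(any(grepl("prevention rule", r1$log)))
  expect_error(
    run_pipeline(list(paths = list(encounters = "nope.csv",
                                   institutions = "nope.csv",
                                   provincial = "nope.yaml"))),
    "stage 'ingest'.*encounters")
})

test_that("pipeline artifacts are written and byte-stable", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(generator = tiny_config(seed = 31L), out = out1)
  suppressWarnings(run_pipeline(config))
  config$out <- out2
  suppressWarnings(run_pipeline(config))
  for (f in c("cube_children.csv", "table_provider.csv", "coefficients.yaml")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})
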