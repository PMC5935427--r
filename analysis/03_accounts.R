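#!/usr/bin/env Rscript
# Step 3 — top-down accounts: scale the provincial aggregates into the CHE
# cube and restrict it to children (ages 0-14 inclusive).
#
# The cube is indexed by provider type x function x financing scheme x ICD-10
# chapter x age bin. Because step 01 generated the whole universe, the
# estimated cube can be compared against exhaustive ground truth here.

suppressMessages(library(checounts))

dat <- "results/data"
enc <- read_encounters(file.path(dat, "survey_encounters.csv"))$records
inst <- read_institution_finance(file.path(dat, "survey_institutions.csv"),
                                 file.path(dat, "survey_projects.csv"))$records
prov <- read_provincial(file.path(dat, "provincial.yaml"))
coef <- read_coefficients("results/coefficients.yaml")

cube <- compute_che(prov, enc, inst, coef, prevention_rule = "max")
kids <- restrict_to_children(cube)
write_cube(cube, "results/cube_total_population.csv")
write_cube(kids, "results/cube_children.csv")

cat(sprintf("CHE, total population: %.2f M CNY across %d cube cells\n",
            cube_total(cube) / 1e6, nrow(cube)))
cat(sprintf("CHE, children 0-14:   %.2f M CNY (%.2f%% of total)\n",
            cube_total(kids) / 1e6, 100 * cube_total(kids) / cube_total(cube)))

fin <- cube_margin(kids, "financing")
for (i in seq_len(nrow(fin))) {
  cat(sprintf("  children financing, %-10s: %6.2f M CNY (%.1f%%)\n",
              fin$financing[i], fin$amount_cny[i] / 1e6,
              100 * fin$amount_cny[i] / cube_total(kids)))
}

# estimation error against the generated truth
truth <- read_cube(file.path(dat, "census_truth_cube.csv"))
truth_kids <- read_cube(file.path(dat, "census_truth_children_cube.csv"))
est <- 100 * cube_total(kids) / cube_total(cube)
tru <- 100 * cube_total(truth_kids) / cube_total(truth)
cat(sprintf("children's share: estimated %.2f%% vs true %.2f%% (error %.2f pp)\n",
            est, tru, abs(est - tru)))
cat("wrote results/cube_total_population.csv and results/cube_children.csv\n")
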