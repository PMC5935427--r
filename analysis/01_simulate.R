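#!/usr/bin/env Rscript
# Step 1 — simulate a province and draw the institution survey.
#
# Builds a synthetic provincial census (institutions, every service
# encounter, finance sheets, yearbook-style aggregates, ground-truth accounts
# cube) and draws a 30% multistage institution sample from it, mimicking a
# provincial health-accounts survey. The survey files written here are the
# inputs of steps 02-04; the census ground truth is kept so later steps can
# report estimation error against it.

suppressMessages(library(checounts))

seed <- as.integer(Sys.getenv("CHE_SEED", "2014"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
census <- generate_dataset(cfg)
survey <- draw_survey(census, sampling_plan(institution_fraction = 0.3),
                      seed = seed + 1L)

cat(sprintf(
  "census: %d institutions in %d cities (+%d provincial hospitals), %d encounters\n",
  nrow(census$institutions), cfg$n_cities, cfg$n_provincial_hospitals,
  nrow(census$encounters)))
cat(sprintf("survey: %d institutions, %d encounters (30%% institution sample)\n",
            nrow(survey$institutions), nrow(survey$encounters)))

write_encounters(survey$encounters, file.path(out, "survey_encounters.csv"))
write_institution_finance(survey$institutions,
                          file.path(out, "survey_institutions.csv"),
                          file.path(out, "survey_projects.csv"))
write_provincial(census$provincial, file.path(out, "provincial.yaml"))
write_cube(census$truth, file.path(out, "census_truth_cube.csv"))
write_cube(restrict_to_children(census$truth),
           file.path(out, "census_truth_children_cube.csv"))

kids_truth <- restrict_to_children(census$truth)
cat(sprintf("ground truth: CHE %.2f M CNY, children %.2f M CNY (%.2f%% of total)\n",
            cube_total(census$truth) / 1e6, cube_total(kids_truth) / 1e6,
            100 * cube_total(kids_truth) / cube_total(census$truth)))
cat("wrote survey + truth files to", out, "\n")
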