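#!/usr/bin/env Rscript
# Step 2 — estimate the allocation coefficients from the survey.
#
# Reads the survey files written by 01_simulate.R, validates them, tallies
# the quantities the coefficient formulas need and estimates
#   alpha_i  curative share of outpatient income   (1 - E_POI/E_TOI)
#   alpha_s  curative share of the basic subsidy   (N_MS/(N_MS+N_PHS))
#   upsilon  curative share of outpatient visits   (1 - N_POV/N_TOV)
#   beta     inpatient share of curative workload  (N_IBD/(N_IBD+N_IOV*K))
# per provider stratum and pooled, with provenance.

suppressMessages(library(checounts))

dat <- "results/data"
enc <- read_encounters(file.path(dat, "survey_encounters.csv"))
inst <- read_institution_finance(file.path(dat, "survey_institutions.csv"),
                                 file.path(dat, "survey_projects.csv"))
prov <- read_provincial(file.path(dat, "provincial.yaml"))
stopifnot(enc$summary$rows_rejected == 0, inst$summary$rows_rejected == 0)
cat(sprintf("read %d encounters from %d institutions, 0 rejected\n",
            enc$summary$rows_kept, inst$summary$rows_kept))

tallies <- tally_survey(enc$records, inst$records, target_age_max = 14)
coef <- estimate_coefficients(tallies, prov, kappa = 0.1)

p <- coef$pooled
cat(sprintf("pooled: alpha_i=%.4f  alpha_s=%.4f  upsilon=%.4f  beta=%.4f\n",
            p$alpha_i, p$alpha_s, p$upsilon, p$beta))
cat(sprintf("N_IOV (curative outpatient visits, province) = %.0f of N_OV = %d\n",
            p$n_iov, coef$provenance$provincial_n_ov))
cat(sprintf("child contacts in survey: N_MS=%d, N_PHS=%d\n",
            coef$provenance$n_ms, coef$provenance$n_phs))

write_coefficients(coef, "results/coefficients.yaml")
readr::write_csv(coef$by_stratum, "results/coefficients_by_stratum.csv")
cat("wrote results/coefficients.yaml and results/coefficients_by_stratum.csv\n")
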