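#!/usr/bin/env Rscript
# Stage 1: generate the synthetic claims-style cohort.
#
# Draws a 20 000-patient inpatient oncology cohort (ages 0-29) whose age,
# sex, disease, emetic-risk and regimen marginals default to the published
# audit's marginals, and writes the two claims-style tables
# (patients.csv, administrations.csv) under results/cohort/.

suppressMessages(library(cinvaudit))

cfg <- cohort_config(n_patients = 20000, seed = 20100701)
cohort <- generate_cohort(cfg)
paths <- write_cohort(cohort$patients, cohort$events, "results/cohort")

cat("Generated", nrow(cohort$patients), "patients and",
    nrow(cohort$events), "administration events\n")
cat("Age groups:\n")
print(table(age_group(cohort$patients$age_years)))
cat(sprintf("Male fraction: %.3f\n",
            mean(cohort$patients$sex == "male")))
cat("Planted reporting strata:\n")
print(table(cohort$truth$stratum))
cat("Tables written:", paste(paths, collapse = ", "), "\n")
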