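#!/usr/bin/env Rscript
# Stage 2: apply the cohort inclusion criteria and classify first-day
# emetogenic risk.
#
# Reads the claims-style tables from stage 1, keeps patients under 30 with
# at least one parenteral chemotherapy administration, classifies every
# parenteral chemotherapy drug on each patient's first treatment day
# (Dubois body-surface-area normalization for the cyclophosphamide and
# cytarabine dose rules) and aggregates to the day-level maximum risk.

suppressMessages(library(cinvaudit))

cohort <- read_cohort("results/cohort")
report <- validate_tables(cohort$patients, cohort$events)
stopifnot(nrow(report) == 0)
cat("Input tables validate cleanly\n")

sel <- select_cohort(cohort$patients, cohort$events)
cat("Selected", nrow(sel$patients), "of", nrow(cohort$patients),
    "patients (<30 y with parenteral chemotherapy)\n")

risk <- assign_cohort_risk(sel$patients, sel$events)
write.csv(risk, "results/risk.csv", row.names = FALSE)

cat("First-day emetic risk distribution:\n")
print(table(factor(risk$day_category, levels = rev(risk_levels))))
cat("Reporting strata (high risk split at age 18):\n")
print(table(risk$stratum))
cat("Written: results/risk.csv\n")
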