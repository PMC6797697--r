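#!/usr/bin/env Rscript
# Stage 4: stratified summaries and the concordance factor model.
#
# Produces the regimen frequency table with Wilson 95% CIs, per-stratum
# concordance rates under both guideline editions, per-class
# overuse/underuse rates, and the logistic regression of 2017-edition
# concordance on age group, sex, emetic risk category and disease class
# (references: 25-29 y, male, minimal risk, solid tumors).

suppressMessages(library(cinvaudit))

cohort <- read_cohort("results/cohort")
sel <- select_cohort(cohort$patients, cohort$events)
res <- evaluate_cohort(sel$patients, sel$events)

tab <- summarize_regimens(res, ci = "wilson")
write.csv(tab, "results/summary.csv", row.names = FALSE)

rates <- do.call(rbind, lapply(c("asco2006", "asco2017"), function(v) {
  r <- concordance_rates(res, v)
  r$version <- v
  r
}))
write.csv(rates, "results/rates.csv", row.names = FALSE)
cat("Concordance rates by stratum (synthetic cohort):\n")
print(as.data.frame(rates[, c("version", "stratum", "n", "rate",
                              "ci_low", "ci_high")]), row.names = FALSE,
      digits = 3)

mis <- misuse_rates(res, "asco2017", "stratum")
write.csv(mis, "results/misuse.csv", row.names = FALSE)
cat("\nSteroid underuse by stratum (%):\n")
st <- mis[mis$class == "steroid", c("stratum", "underuse_pct")]
print(as.data.frame(st), row.names = FALSE, digits = 3)

model <- fit_concordance_model(res, sel$patients, version = "asco2017")
jsonlite::write_json(
  list(version = model$version, n = model$n, terms = model$report),
  "results/model.json", auto_unbox = TRUE, digits = NA, na = "null")
cat("\n")
print(model)
cat("\nWritten: results/summary.csv, rates.csv, misuse.csv, model.json\n")
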