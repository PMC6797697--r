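# Hand-transcribed concordance/discordance marks for every printed regimen
# row of the published audit's prescription table (5 strata, both ASCO
# editions). Independent of the package's rule-set data files: this is the
# zero-tolerance oracle for the rule engine.
published_marks <- function() {
  tibble::tribble(
    ~stratum,       ~regimen,                ~c2006, ~c2017,
    "minimal",      "NK1RA+5HT3RA+steroid",  FALSE,  FALSE,
    "minimal",      "5HT3RA+steroid",        FALSE,  FALSE,
    "minimal",      "NK1RA+5HT3RA",          FALSE,  FALSE,
    "minimal",      "NK1RA",                 FALSE,  FALSE,
    "minimal",      "5HT3RA",                FALSE,  FALSE,
    "minimal",      "steroid",               FALSE,  FALSE,
    "minimal",      "none",                  TRUE,   TRUE,
    "low",          "NK1RA+5HT3RA+steroid",  FALSE,  FALSE,
    "low",          "5HT3RA+steroid",        FALSE,  FALSE,
    "low",          "NK1RA+5HT3RA",          FALSE,  FALSE,
    "low",          "NK1RA+steroid",         FALSE,  FALSE,
    "low",          "NK1RA",                 FALSE,  FALSE,
    "low",          "5HT3RA",                FALSE,  TRUE,
    "low",          "steroid",               TRUE,   TRUE,
    "low",          "none",                  FALSE,  FALSE,
    "moderate",     "NK1RA+5HT3RA+steroid",  FALSE,  FALSE,
    "moderate",     "NK1RA+steroid",         FALSE,  FALSE,
    "moderate",     "NK1RA+5HT3RA",          FALSE,  FALSE,
    "moderate",     "5HT3RA+steroid",        TRUE,   TRUE,
    "moderate",     "NK1RA",                 FALSE,  FALSE,
    "moderate",     "5HT3RA",                FALSE,  FALSE,
    "moderate",     "steroid",               FALSE,  FALSE,
    "moderate",     "none",                  FALSE,  FALSE,
    "high_adult",   "NK1RA+5HT3RA+steroid",  TRUE,   TRUE,
    "high_adult",   "5HT3RA+steroid",        FALSE,  FALSE,
    "high_adult",   "NK1RA+5HT3RA",          FALSE,  FALSE,
    "high_adult",   "NK1RA+steroid",         FALSE,  FALSE,
    "high_adult",   "NK1RA",                 FALSE,  FALSE,
    "high_adult",   "5HT3RA",                FALSE,  FALSE,
    "high_adult",   "steroid",               FALSE,  FALSE,
    "high_adult",   "none",                  FALSE,  FALSE,
    "high_under18", "NK1RA+5HT3RA+steroid",  FALSE,  TRUE,
    "high_under18", "5HT3RA+steroid",        TRUE,   FALSE,
    "high_under18", "NK1RA+5HT3RA",          FALSE,  FALSE,
    "high_under18", "NK1RA+steroid",         FALSE,  FALSE,
    "high_under18", "NK1RA",                 FALSE,  FALSE,
    "high_under18", "5HT3RA",                FALSE,  FALSE,
    "high_under18", "steroid",               FALSE,  FALSE,
    "high_under18", "none",                  FALSE,  FALSE
  )
}

# (category, age stratum) cell for a reporting stratum
stratum_cell <- function(stratum) {
  switch(stratum,
         high_adult = c("high", "adult"),
         high_under18 = c("high", "under18"),
         c(stratum, "adult"))
}

# Brute-force Newton-Raphson maximiser of the logistic log-likelihood,
# written independently of stats::glm as a cross-check oracle.
logistic_newton <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - p))
    W <- p * (1 - p)
    H <- t(X) %*% (X * W)
    delta <- solve(H, grad)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  beta
}

# small hand-built cohort: one patient per row spec
toy_patient <- function(id, age, sex = "male", disease = "solid",
                        height = 150, weight = 45) {
  tibble::tibble(patient_id = id, age_years = as.integer(age), sex = sex,
                 disease_class = disease, height_cm = height,
                 weight_kg = weight)
}

toy_event <- function(id, day, drug, route = "parenteral", dose = 50,
                      class = "chemotherapy") {
  tibble::tibble(patient_id = id, day_index = as.integer(day),
                 drug_name = drug, route = route, dose_mg = dose,
                 event_class = class)
}
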