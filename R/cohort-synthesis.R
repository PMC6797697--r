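# Age-banded growth-reference midpoints (unisex to age 12, sex-shifted
# after) used for anthropometric draws; only BSA plausibility matters
# downstream. Columns: mean height cm, SD height, mean weight kg; weight
# SD is 12% of the mean. Truncation at +-3 SD.
growth_reference <- data.frame(
  age = 0:29,
  height_mean = c(68, 76, 87, 95, 102, 109, 115, 121, 127, 132, 138, 143,
                  150, 156, 161, 164, 166, 167, 168, 168,
                  rep(168, 10)),
  height_sd = c(3, 3, 3.5, 4, 4, 4.5, 4.5, 5, 5, 5.5, 6, 6.5, 7, 7.5, 7.5,
                7, 7, 7, 7, 7, rep(7, 10)),
  weight_mean = c(8, 10, 12, 14, 16, 18, 21, 23, 26, 29, 32, 36, 41, 46,
                  50, 54, 57, 59, 60, 61, rep(62, 10))
)

#' Reference regimen frequencies from a published nationwide audit
#'
#' Per-stratum prophylactic-regimen frequencies (percent, with 95% CIs and
#' stratum sizes) transcribed from a published nationwide audit of
#' antiemetic prescribing in Japanese inpatients under 30 years of age
#' receiving chemotherapy (2010-2016, N = 21 106). These frequencies serve
#' two roles: they are the default regimen weights of the synthetic cohort
#' generator, and feeding them through the rule engine reproduces the
#' published category-level concordance rates (see
#' [concordance_from_frequencies()]).
#'
#' @return tibble with columns `stratum`, `regimen`, `percent`, `ci_low`,
#'   `ci_high`, `n_stratum`.
#' @export
reference_regimen_frequencies <- function() {
  path <- system.file("extdata", "regimen_frequency_reference.csv",
                      package = "cinvaudit")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

default_regimen_weights <- function() {
  f <- reference_regimen_frequencies()
  out <- lapply(split(f, f$stratum), function(b) {
    w <- stats::setNames(b$percent, b$regimen)
    w / sum(w)
  })
  out[cohort_strata]
}

#' Build a cohort generator configuration
#'
#' Defaults are the marginals of the reference audit: seven age groups
#' (0-2 through 25-29) with the published patient counts, 53.4% male, the
#' published emetic-risk-category split, disease class drawn conditionally
#' on risk category (high risk mostly solid tumors, low risk mostly
#' hematologic, matching the published cross-tabulation's direction), and
#' per-stratum regimen weights equal to the published regimen frequencies.
#'
#' @param n_patients number of patients to generate (>= 1).
#' @param seed integer seed; identical configs (including seed) produce
#'   byte-identical output tables.
#' @param age_group_weights 7 nonnegative weights over the age groups
#'   0-2, 3-4, 5-9, 10-14, 15-19, 20-24, 25-29; must sum to 1 (1e-9).
#' @param sex_split probability of male, in `[0, 1]`.
#' @param disease_weights 3 nonnegative weights over (solid, hematologic,
#'   brain); used only when `disease_by_risk` is `NULL`.
#' @param disease_by_risk 4x3 matrix of disease weights conditional on risk
#'   category (rows high, moderate, low, minimal; columns solid,
#'   hematologic, brain), each row summing to 1.
#' @param risk_category_weights 4 nonnegative weights over (high, moderate,
#'   low, minimal) for the planted first-day risk category; must sum to 1.
#' @param regimen_weights named list mapping each of the five reporting
#'   strata (`minimal`, `low`, `moderate`, `high_adult`, `high_under18`)
#'   to a named weight vector over regimen labels.
#' @param cycle2_prob probability of a second chemotherapy cycle 21 days
#'   after the first (later cycles get independent regimen draws; only the
#'   first day enters the analysis).
#' @param extra_minimal_prob probability of an additional same-day
#'   minimal-risk drug (vincristine), exercising the max-aggregation.
#' @param oral_chemo_prob probability of a same-day oral chemotherapy
#'   administration (excluded from risk scoring).
#' @param other_event_prob probability of a non-chemo, non-antiemetic
#'   administration (event_class `other`).
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          age_group_weights = c(2480, 1417, 2436, 2528,
                                                3112, 3513, 5620) / 21106,
                          sex_split = 0.534,
                          disease_weights = c(solid = 9562, hematologic = 9463,
                                              brain = 2081) / 21106,
                          disease_by_risk = NULL,
                          risk_category_weights = c(high = 6661,
                                                    moderate = 7188,
                                                    low = 5806,
                                                    minimal = 1451) / 21106,
                          regimen_weights = default_regimen_weights(),
                          cycle2_prob = 0.4,
                          extra_minimal_prob = 0.25,
                          oral_chemo_prob = 0.1,
                          other_event_prob = 0.05) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 1) {
    stop("configuration error: n_patients must be >= 1", call. = FALSE)
  }
  check_weights <- function(w, k, what) {
    if (length(w) != k || any(!is.finite(w)) || any(w < 0) ||
        abs(sum(w) - 1) > 1e-9) {
      stop("configuration error: ", what, " must be ", k,
           " nonnegative weights summing to 1", call. = FALSE)
    }
  }
  check_weights(age_group_weights, 7, "age_group_weights")
  check_weights(risk_category_weights, 4, "risk_category_weights")
  check_weights(disease_weights, 3, "disease_weights")
  if (!is.numeric(sex_split) || sex_split < 0 || sex_split > 1) {
    stop("configuration error: sex_split must be in [0, 1]", call. = FALSE)
  }
  if (is.null(disease_by_risk)) {
    disease_by_risk <- rbind(
      high     = c(solid = 0.724, hematologic = 0.180, brain = 0.096),
      moderate = c(solid = 0.400, hematologic = 0.422, brain = 0.178),
      low      = c(solid = 0.200, hematologic = 0.732, brain = 0.068),
      minimal  = c(solid = 0.300, hematologic = 0.586, brain = 0.114)
    )
  }
  stopifnot(is.matrix(disease_by_risk), dim(disease_by_risk) == c(4, 3))
  for (i in 1:4) check_weights(disease_by_risk[i, ], 3,
                               paste0("disease_by_risk[", i, ", ]"))
  if (!setequal(names(regimen_weights), cohort_strata)) {
    stop("configuration error: regimen_weights must have one entry per ",
         "stratum: ", paste(cohort_strata, collapse = ", "), call. = FALSE)
  }
  for (s in cohort_strata) {
    w <- regimen_weights[[s]]
    if (is.null(names(w)) || any(w < 0) || sum(w) <= 0 ||
        !all(names(w) %in% all_regimens())) {
      stop("configuration error: regimen_weights$", s,
           " must be nonnegative, named by regimen labels", call. = FALSE)
    }
    regimen_weights[[s]] <- w / sum(w)
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    age_group_weights = age_group_weights, sex_split = sex_split,
    disease_weights = disease_weights, disease_by_risk = disease_by_risk,
    risk_category_weights = risk_category_weights,
    regimen_weights = regimen_weights,
    cycle2_prob = cycle2_prob, extra_minimal_prob = extra_minimal_prob,
    oral_chemo_prob = oral_chemo_prob, other_event_prob = other_event_prob
  ), class = "cohort_config")
}

# truncated-normal draw (+-3 SD), vectorised
rnorm_trunc <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, mean - 3 * sd), mean + 3 * sd)
}

# sample a regimen label per patient given stratum, using per-stratum
# weights; deterministic for a fixed RNG state
sample_regimens <- function(stratum, weights) {
  out <- character(length(stratum))
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    w <- weights[[s]]
    out[idx] <- sample(names(w), length(idx), replace = TRUE, prob = w)
  }
  out
}

# per-patient chemotherapy drug + dose (mg/m2) consistent with the planted
# risk category; dose-rule drugs are drawn with a safety margin around the
# thresholds so that mg-rounding cannot flip the category
draw_chemo <- function(category, n) {
  drug <- character(n)
  per_m2 <- numeric(n)
  u <- stats::runif(n)
  hi <- category == "high"
  drug[hi] <- ifelse(u[hi] < 0.3, "cyclophosphamide", "cisplatin")
  per_m2[hi] <- ifelse(u[hi] < 0.3, stats::runif(sum(hi), 1505, 3000),
                       stats::runif(sum(hi), 60, 100))
  mo <- category == "moderate"
  drug[mo] <- ifelse(u[mo] < 0.15, "cyclophosphamide",
                     ifelse(u[mo] < 0.30, "cytarabine", "doxorubicin"))
  per_m2[mo] <- ifelse(u[mo] < 0.15, stats::runif(sum(mo), 500, 1495),
                       ifelse(u[mo] < 0.30, stats::runif(sum(mo), 1005, 3000),
                              stats::runif(sum(mo), 30, 60)))
  lo <- category == "low"
  drug[lo] <- ifelse(u[lo] < 0.3, "cytarabine", "etoposide")
  per_m2[lo] <- ifelse(u[lo] < 0.3, stats::runif(sum(lo), 75, 995),
                       stats::runif(sum(lo), 60, 120))
  mi <- category == "minimal"
  drug[mi] <- "vincristine"
  per_m2[mi] <- stats::runif(sum(mi), 1, 1.5)
  list(drug = drug, per_m2 = per_m2)
}

# antiemetic drug names and doses for one class column; weight/bsa used for
# plausible dosing only
antiemetic_events_for <- function(class, pid, day, weight_kg, bsa) {
  n <- length(pid)
  if (n == 0) {
    return(NULL)
  }
  u <- stats::runif(n)
  if (class == "NK1RA") {
    drug <- ifelse(u < 0.8, "aprepitant", "fosaprepitant")
    route <- ifelse(u < 0.8, "oral", "parenteral")
    dose <- ifelse(u < 0.8, 125, 150)
  } else if (class == "5HT3RA") {
    drug <- ifelse(u < 0.5, "ondansetron", "granisetron")
    route <- rep("parenteral", n)
    dose <- ifelse(u < 0.5, round(pmin(0.15 * weight_kg, 8), 1), 3)
  } else {
    drug <- ifelse(u < 0.9, "dexamethasone", "methylprednisolone")
    route <- rep("parenteral", n)
    dose <- ifelse(u < 0.9, round(pmin(6.6 * bsa, 13.2), 1), 40)
  }
  data.frame(patient_id = pid, day_index = day, drug_name = drug,
             route = route, dose_mg = dose, event_class = "antiemetic",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic DPC-like oncology cohort
#'
#' Emulates the structure of inpatient administrative-claims chemotherapy
#' and antiemetic records for patients under 30: a demographics table and
#' a dated administration table with same-day co-prescription patterns.
#' Age, sex, disease and emetic-risk marginals follow the configuration
#' (defaults = the published audit's marginals); each patient receives at
#' least one parenteral chemotherapy administration whose drug and dose
#' are chosen so that the first treatment day's aggregated risk category
#' follows `risk_category_weights`, and same-day prophylactic antiemetics
#' are drawn from the per-stratum `regimen_weights`. Later cycles, oral
#' chemotherapy, extra minimal-risk agents and unrelated administrations
#' are added as configured noise to exercise the selection logic.
#'
#' @param config a `cohort_config`.
#' @return list with `patients` (tibble: patient_id, age_years, sex,
#'   disease_class, height_cm, weight_kg) and `events` (tibble:
#'   patient_id, day_index, drug_name, route, dose_mg, event_class),
#'   plus attribute-free truth columns available via the returned
#'   `truth` tibble (patient_id, planted stratum and regimen).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%06d", seq_len(n))

  grp <- sample(seq_along(age_group_labels), n, replace = TRUE,
                prob = config$age_group_weights)
  lo_age <- age_group_breaks[grp]
  hi_age <- age_group_breaks[grp + 1] - 1
  age <- lo_age + floor(stats::runif(n) * (hi_age - lo_age + 1))
  sex <- ifelse(stats::runif(n) < config$sex_split, "male", "female")

  risk <- sample(c("high", "moderate", "low", "minimal"), n, replace = TRUE,
                 prob = config$risk_category_weights)
  disease <- character(n)
  for (r in rownames(config$disease_by_risk)) {
    idx <- which(risk == r)
    disease[idx] <- sample(colnames(config$disease_by_risk), length(idx),
                           replace = TRUE, prob = config$disease_by_risk[r, ])
  }

  gr <- growth_reference[match(age, growth_reference$age), ]
  sex_shift <- ifelse(age >= 13, ifelse(sex == "male", 6, -6), 0)
  height <- round(rnorm_trunc(n, gr$height_mean + sex_shift, gr$height_sd), 1)
  wshift <- ifelse(age >= 13, ifelse(sex == "male", 4, -3), 0)
  weight <- round(rnorm_trunc(n, gr$weight_mean + wshift,
                              0.12 * gr$weight_mean), 1)
  height <- pmax(height, 45)
  weight <- pmax(weight, 2.5)
  bsa <- compute_bsa(height, weight, "dubois")

  stratum <- reporting_stratum(risk, age_stratum(age))
  regimen <- sample_regimens(stratum, config$regimen_weights)

  first_day <- sample(0:20, n, replace = TRUE)
  chemo <- draw_chemo(risk, n)
  dose <- round(chemo$per_m2 * bsa, 1)

  patients <- tibble::tibble(
    patient_id = pid, age_years = as.integer(age), sex = sex,
    disease_class = disease, height_cm = height, weight_kg = weight
  )

  ev <- list(data.frame(
    patient_id = pid, day_index = first_day, drug_name = chemo$drug,
    route = "parenteral", dose_mg = dose, event_class = "chemotherapy",
    stringsAsFactors = FALSE
  ))

  extra <- which(stats::runif(n) < config$extra_minimal_prob &
                   chemo$drug != "vincristine")
  if (length(extra) > 0) {
    ev[[length(ev) + 1]] <- data.frame(
      patient_id = pid[extra], day_index = first_day[extra],
      drug_name = "vincristine", route = "parenteral",
      dose_mg = round(pmin(1.5 * bsa[extra], 2), 2),
      event_class = "chemotherapy", stringsAsFactors = FALSE)
  }
  oral <- which(stats::runif(n) < config$oral_chemo_prob)
  if (length(oral) > 0) {
    ev[[length(ev) + 1]] <- data.frame(
      patient_id = pid[oral], day_index = first_day[oral],
      drug_name = "mercaptopurine", route = "oral",
      dose_mg = round(50 * bsa[oral], 1),
      event_class = "chemotherapy", stringsAsFactors = FALSE)
  }
  other <- which(stats::runif(n) < config$other_event_prob)
  if (length(other) > 0) {
    ev[[length(ev) + 1]] <- data.frame(
      patient_id = pid[other], day_index = first_day[other],
      drug_name = "acetaminophen", route = "oral", dose_mg = 400,
      event_class = "other", stringsAsFactors = FALSE)
  }

  for (cls in antiemetic_classes) {
    # class names are not substrings of one another, so fixed grepl on the
    # canonical label is an exact membership test
    idx <- which(grepl(cls, regimen, fixed = TRUE))
    ae <- antiemetic_events_for(cls, pid[idx], first_day[idx],
                                weight[idx], bsa[idx])
    if (!is.null(ae)) ev[[length(ev) + 1]] <- ae
  }

  # later cycle: same drug/dose, independent regimen draw; exists only to
  # exercise first-day selection
  cyc <- which(stats::runif(n) < config$cycle2_prob)
  if (length(cyc) > 0) {
    day2 <- first_day[cyc] + 21L
    ev[[length(ev) + 1]] <- data.frame(
      patient_id = pid[cyc], day_index = day2, drug_name = chemo$drug[cyc],
      route = "parenteral", dose_mg = dose[cyc],
      event_class = "chemotherapy", stringsAsFactors = FALSE)
    reg2 <- sample_regimens(stratum[cyc], config$regimen_weights)
    for (cls in antiemetic_classes) {
      idx <- which(grepl(cls, reg2, fixed = TRUE))
      ae <- antiemetic_events_for(cls, pid[cyc][idx], day2[idx],
                                  weight[cyc][idx], bsa[cyc][idx])
      if (!is.null(ae)) ev[[length(ev) + 1]] <- ae
    }
  }

  events <- tibble::as_tibble(do.call(rbind, ev))
  events <- events[order(events$patient_id, events$day_index,
                         events$event_class, events$drug_name), ]
  list(
    patients = patients,
    events = events,
    truth = tibble::tibble(patient_id = pid, stratum = stratum,
                           regimen = regimen)
  )
}

#' Apply the cohort inclusion criteria
#'
#' Retains patients under 30 years of age with at least one parenteral
#' chemotherapy administration (oral-only chemotherapy is excluded), and
#' returns each retained patient's first parenteral chemotherapy day.
#'
#' @param patients patient table.
#' @param events administration event table; every event must reference an
#'   existing patient.
#' @return list with filtered `patients`, `events` (restricted to retained
#'   patients), and `first_day` (tibble patient_id, first_day).
#' @export
select_cohort <- function(patients, events) {
  orphan <- setdiff(unique(events$patient_id), patients$patient_id)
  if (length(orphan) > 0) {
    stop(structure(class = c("cinv_integrity_error", "error", "condition"),
                   list(message = paste0(
                     "events reference unknown patient id(s): ",
                     paste(utils::head(orphan, 10), collapse = ", "),
                     if (length(orphan) > 10) " ..." else ""),
                     call = NULL)))
  }
  chemo <- events[events$event_class == "chemotherapy" &
                    events$route == "parenteral", , drop = FALSE]
  keep <- patients$age_years < 30 & patients$age_years >= 0 &
    patients$patient_id %in% chemo$patient_id
  patients <- patients[keep, , drop = FALSE]
  events <- events[events$patient_id %in% patients$patient_id, , drop = FALSE]
  chemo <- chemo[chemo$patient_id %in% patients$patient_id, , drop = FALSE]
  if (nrow(chemo) == 0) {
    fd <- tibble::tibble(patient_id = character(0), first_day = integer(0))
  } else {
    m <- tapply(chemo$day_index, chemo$patient_id, min)
    fd <- tibble::tibble(patient_id = names(m), first_day = as.integer(m))
    fd <- fd[match(patients$patient_id, fd$patient_id), ]
  }
  list(patients = tibble::as_tibble(patients),
       events = tibble::as_tibble(events), first_day = fd)
}

#' Write / read a cohort as CSV tables
#'
#' `write_cohort()` writes `patients.csv` and `administrations.csv`
#' (RFC 4180, UTF-8, header row) into a directory; identical inputs write
#' byte-identical files. `read_cohort()` reads them back, coercing types;
#' missing height or weight values are accepted but flagged with a warning
#' since dose-per-m2 risk rules cannot be applied without them.
#'
#' @param patients,events cohort tables as returned by [generate_cohort()].
#' @param dir directory to write into / read from (created if needed).
#' @return `write_cohort()`: the two file paths, invisibly.
#'   `read_cohort()`: list with `patients` and `events` tibbles.
#' @export
write_cohort <- function(patients, events, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pf <- file.path(dir, "patients.csv")
  ef <- file.path(dir, "administrations.csv")
  utils::write.csv(patients, pf, row.names = FALSE, quote = TRUE, eol = "\n")
  utils::write.csv(events, ef, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(c(patients = pf, events = ef))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pf <- file.path(dir, "patients.csv")
  ef <- file.path(dir, "administrations.csv")
  for (f in c(pf, ef)) {
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  }
  patients <- utils::read.csv(pf, stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
  events <- utils::read.csv(ef, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character"))
  n_miss <- sum(is.na(patients$height_cm) | is.na(patients$weight_kg))
  if (n_miss > 0) {
    warning(n_miss, " patient(s) have missing height or weight; ",
            "dose-dependent risk rules will fail for them", call. = FALSE)
  }
  list(patients = tibble::as_tibble(patients),
       events = tibble::as_tibble(events))
}

#' Simulate covariates and concordance outcomes from a known logistic model
#'
#' Draws the four patient factors (age group, sex, risk category, disease
#' class) independently from the reference marginals, then draws the
#' concordance outcome from a logistic model with user-specified effects.
#' Used for parameter-recovery and CI-coverage studies of
#' [fit_concordance_model()], where the generative odds ratios are known.
#'
#' @param n number of patients.
#' @param coefs named list of per-covariate log-odds-ratio vectors, e.g.
#'   `list(age_group = c("0-2" = log(0.53)))`; levels not named have
#'   effect 0, reference levels (25-29, male, minimal, solid) always 0.
#' @param intercept log-odds of concordance at the reference levels.
#' @param seed integer seed.
#' @return tibble with `age_group`, `sex`, `day_category`, `disease`
#'   factors and logical `concordant`.
#' @export
simulate_concordance_data <- function(n, coefs = list(), intercept = 0,
                                      seed = 1L) {
  set.seed(seed)
  cfg <- cohort_config(1)  # reference marginals
  ag <- sample(age_group_labels, n, replace = TRUE,
               prob = cfg$age_group_weights)
  sex <- ifelse(stats::runif(n) < cfg$sex_split, "male", "female")
  risk <- sample(c("high", "moderate", "low", "minimal"), n, replace = TRUE,
                 prob = cfg$risk_category_weights)
  disease <- sample(c("solid", "hematologic", "brain"), n, replace = TRUE,
                    prob = cfg$disease_weights)
  lp <- rep(intercept, n)
  add_effect <- function(lp, values, eff) {
    if (is.null(eff)) return(lp)
    for (lv in names(eff)) lp <- lp + eff[[lv]] * (values == lv)
    lp
  }
  lp <- add_effect(lp, ag, coefs$age_group)
  lp <- add_effect(lp, sex, coefs$sex)
  lp <- add_effect(lp, risk, coefs$day_category)
  lp <- add_effect(lp, disease, coefs$disease)
  tibble::tibble(
    age_group = factor(ag, levels = age_group_labels),
    sex = factor(sex, levels = c("male", "female")),
    day_category = factor(risk, levels = c("minimal", "low", "moderate",
                                           "high")),
    disease = factor(disease, levels = c("solid", "hematologic", "brain")),
    concordant = stats::rbinom(n, 1, stats::plogis(lp)) == 1
  )
}
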