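#' Body surface area
#'
#' Computes BSA in square metres from height and weight by the Dubois or
#' Mosteller formula. Dubois is the default used throughout the package for
#' the dose-per-m2 emetic-risk rules; Mosteller, common in pediatrics, is
#' selectable and agrees with Dubois to within a few percent over the
#' pediatric/young-adult range.
#'
#' Dubois: `0.007184 * height_cm^0.725 * weight_kg^0.425`.
#' Mosteller: `sqrt(height_cm * weight_kg / 3600)`.
#'
#' @param height_cm positive numeric vector, height in centimetres.
#' @param weight_kg positive numeric vector, weight in kilograms.
#' @param formula `"dubois"` (default) or `"mosteller"`.
#' @return numeric vector of BSA in m^2.
#' @export
#' @examples
#' compute_bsa(60, 60, "mosteller")  # exactly 1
#' compute_bsa(180, 70)              # about 1.886
compute_bsa <- function(height_cm, weight_kg, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (!is.numeric(height_cm) || !is.numeric(weight_kg)) {
    stop("height_cm and weight_kg must be numeric", call. = FALSE)
  }
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height_cm and weight_kg must be finite and strictly positive",
         call. = FALSE)
  }
  switch(formula,
    dubois    = 0.007184 * height_cm^0.725 * weight_kg^0.425,
    mosteller = sqrt(height_cm * weight_kg / 3600)
  )
}

#' Load a drug risk / antiemetic class map
#'
#' The map is a YAML data file with three sections: `chemotherapy`
#' (drug name -> fixed emetic risk category), `dose_rules` (drugs whose
#' category depends on the administered dose per m2 of body surface), and
#' `antiemetics` (drug name -> antiemetic class). It is data, not code, so
#' users can align the classification with any guideline edition. The
#' shipped default covers common pediatric oncology drugs and carries the
#' two dose-dependent entries: cyclophosphamide (>=1500 mg/m2 high,
#' otherwise moderate) and cytarabine (>1000 mg/m2 moderate, <=1000 low).
#'
#' @param path path to a YAML map; default is the map shipped with the
#'   package.
#' @return a list of class `drug_map` with elements `chemotherapy`,
#'   `dose_rules`, `antiemetics`.
#' @export
load_drug_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_risk_map.yaml", package = "cinvaudit")
  }
  m <- yaml::read_yaml(path)
  for (s in c("chemotherapy", "dose_rules", "antiemetics")) {
    if (is.null(m[[s]])) stop("drug map is missing section '", s, "'",
                              call. = FALSE)
  }
  bad <- setdiff(unlist(m$chemotherapy, use.names = FALSE), risk_levels)
  if (length(bad) > 0) {
    stop("drug map has invalid risk categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (d in names(m$dose_rules)) {
    r <- m$dose_rules[[d]]
    ok <- is.numeric(r$threshold_mg_per_m2) && r$threshold_mg_per_m2 > 0 &&
      r$boundary %in% c("at_or_above", "above") &&
      all(c(r$category_high_side, r$category_low_side) %in% risk_levels)
    if (!ok) stop("invalid dose rule for '", d, "'", call. = FALSE)
  }
  bad <- setdiff(unlist(m$antiemetics, use.names = FALSE), antiemetic_classes)
  if (length(bad) > 0) {
    stop("drug map has invalid antiemetic classes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  names(m$chemotherapy) <- tolower(names(m$chemotherapy))
  names(m$dose_rules) <- tolower(names(m$dose_rules))
  names(m$antiemetics) <- tolower(names(m$antiemetics))
  structure(m, class = "drug_map")
}

#' Classify one chemotherapy administration into an emetic risk category
#'
#' Fixed-category drugs return their mapped category regardless of dose.
#' Dose-rule drugs are classified by `dose_mg / bsa_m2` against the drug's
#' threshold with the guideline's boundary side: cyclophosphamide at or
#' above 1500 mg/m2 is high risk (below, moderate); cytarabine strictly
#' above 1000 mg/m2 is moderate (at or below, low).
#'
#' @param drug_name drug name (matched case-insensitively against the map).
#' @param dose_mg administered dose in milligrams; may be `NA` for
#'   fixed-category drugs.
#' @param bsa_m2 body surface area in m2 (required for dose-rule drugs).
#' @param map a `drug_map` from [load_drug_map()].
#' @return one of `"minimal"`, `"low"`, `"moderate"`, `"high"`.
#' @export
#' @examples
#' m <- load_drug_map()
#' classify_drug("cyclophosphamide", 1500 * 1.6, 1.6, m)  # boundary -> high
#' classify_drug("cytarabine", 1000 * 1.6, 1.6, m)        # boundary -> low
#' classify_drug("vincristine", 2, 1.6, m)                # minimal
classify_drug <- function(drug_name, dose_mg, bsa_m2, map) {
  stopifnot(inherits(map, "drug_map"), length(drug_name) == 1L)
  d <- tolower(drug_name)
  if (!is.null(map$chemotherapy[[d]])) {
    return(map$chemotherapy[[d]])
  }
  rule <- map$dose_rules[[d]]
  if (is.null(rule)) {
    stop("drug '", drug_name, "' is not in the risk map", call. = FALSE)
  }
  if (is.na(dose_mg) || !is.numeric(dose_mg) || dose_mg <= 0) {
    stop("dose-rule drug '", drug_name, "' requires a positive dose_mg",
         call. = FALSE)
  }
  if (is.na(bsa_m2) || !is.numeric(bsa_m2) || bsa_m2 <= 0) {
    stop("dose-rule drug '", drug_name, "' requires a positive bsa_m2 ",
         "(height/weight needed to normalize the dose)", call. = FALSE)
  }
  per_m2 <- dose_mg / bsa_m2
  hit <- if (rule$boundary == "at_or_above") {
    per_m2 >= rule$threshold_mg_per_m2
  } else {
    per_m2 > rule$threshold_mg_per_m2
  }
  if (hit) rule$category_high_side else rule$category_low_side
}

#' Aggregate same-day drug categories to a day-level risk
#'
#' The emetic risk of a treatment day is the highest risk among the
#' chemotherapy drugs given that day, under the total order
#' `minimal < low < moderate < high`.
#'
#' @param categories nonempty character vector of categories.
#' @return the maximal category as a single string.
#' @export
aggregate_day_risk <- function(categories) {
  if (length(categories) == 0) {
    stop("aggregate_day_risk requires at least one category", call. = FALSE)
  }
  as.character(max(risk_factor(categories)))
}

#' First-treatment-day risk assignment for one patient
#'
#' Identifies the patient's first day carrying a parenteral chemotherapy
#' administration, classifies every parenteral chemotherapy drug given that
#' day (oral agents are excluded from risk scoring), aggregates to the
#' day-level maximum, and attaches the <18 / >=18 age stratum.
#'
#' @param patient one-row data frame with `patient_id`, `age_years`,
#'   `height_cm`, `weight_kg`.
#' @param events data frame of administration events (`patient_id`,
#'   `day_index`, `drug_name`, `route`, `dose_mg`, `event_class`).
#' @param map a `drug_map`.
#' @param bsa_formula `"dubois"` (default) or `"mosteller"`.
#' @return a one-row tibble: `patient_id`, `first_day`, `day_category`,
#'   `age_stratum`, `stratum` (five-level reporting stratum), and
#'   `drug_categories` (list column of per-drug categories).
#' @export
assign_first_day_risk <- function(patient, events, map,
                                  bsa_formula = c("dubois", "mosteller")) {
  bsa_formula <- match.arg(bsa_formula)
  stopifnot(nrow(patient) == 1L)
  ev <- events[events$patient_id == patient$patient_id &
                 events$event_class == "chemotherapy" &
                 events$route == "parenteral", , drop = FALSE]
  if (nrow(ev) == 0) {
    stop("patient ", patient$patient_id,
         " has no parenteral chemotherapy events", call. = FALSE)
  }
  first_day <- min(ev$day_index)
  day_ev <- ev[ev$day_index == first_day, , drop = FALSE]
  bsa <- compute_bsa(patient$height_cm, patient$weight_kg, bsa_formula)
  cats <- vapply(seq_len(nrow(day_ev)), function(i) {
    classify_drug(day_ev$drug_name[i], day_ev$dose_mg[i], bsa, map)
  }, character(1))
  day_cat <- aggregate_day_risk(cats)
  stratum <- age_stratum(patient$age_years)
  tibble::tibble(
    patient_id = patient$patient_id,
    first_day = first_day,
    day_category = day_cat,
    age_stratum = stratum,
    stratum = reporting_stratum(day_cat, stratum),
    drug_categories = list(stats::setNames(cats, day_ev$drug_name))
  )
}

#' Vectorised first-day risk assignment for a whole cohort
#'
#' Cohort-scale equivalent of [assign_first_day_risk()]: one row per
#' patient, computed with vectorised classification so that cohorts of
#' 10^5 patients take seconds.
#'
#' @param patients patient table (`patient_id`, `age_years`, `height_cm`,
#'   `weight_kg`, ...); all patients must have at least one parenteral
#'   chemotherapy event (run [select_cohort()] first).
#' @param events administration event table.
#' @inheritParams assign_first_day_risk
#' @return tibble with `patient_id`, `first_day`, `day_category`,
#'   `age_stratum`, `stratum`.
#' @export
assign_cohort_risk <- function(patients, events, map = load_drug_map(),
                               bsa_formula = c("dubois", "mosteller")) {
  bsa_formula <- match.arg(bsa_formula)
  chemo <- events[events$event_class == "chemotherapy" &
                    events$route == "parenteral", , drop = FALSE]
  if (!all(patients$patient_id %in% chemo$patient_id)) {
    missing <- setdiff(patients$patient_id, chemo$patient_id)
    stop("no parenteral chemotherapy events for patient(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  first_day <- tapply(chemo$day_index, chemo$patient_id, min)
  fd <- tibble::tibble(patient_id = names(first_day),
                       first_day = as.integer(first_day))
  day_ev <- dplyr::inner_join(chemo, fd, by = "patient_id")
  day_ev <- day_ev[day_ev$day_index == day_ev$first_day, , drop = FALSE]
  day_ev <- dplyr::left_join(
    day_ev,
    patients[, c("patient_id", "height_cm", "weight_kg")],
    by = "patient_id"
  )

  drug <- tolower(day_ev$drug_name)
  cat <- rep(NA_character_, nrow(day_ev))
  fixed <- unlist(map$chemotherapy)
  idx <- match(drug, names(fixed))
  cat[!is.na(idx)] <- fixed[idx[!is.na(idx)]]
  for (d in names(map$dose_rules)) {
    sel <- which(drug == d)
    if (length(sel) == 0) next
    r <- map$dose_rules[[d]]
    dose <- day_ev$dose_mg[sel]
    hw_ok <- is.finite(day_ev$height_cm[sel]) & is.finite(day_ev$weight_kg[sel])
    if (any(is.na(dose) | dose <= 0) || !all(hw_ok)) {
      stop("dose-rule drug '", d, "' requires positive dose and ",
           "height/weight for body-surface-area normalization", call. = FALSE)
    }
    bsa <- compute_bsa(day_ev$height_cm[sel], day_ev$weight_kg[sel],
                       bsa_formula)
    per_m2 <- dose / bsa
    hit <- if (r$boundary == "at_or_above") per_m2 >= r$threshold_mg_per_m2
           else per_m2 > r$threshold_mg_per_m2
    cat[sel] <- ifelse(hit, r$category_high_side, r$category_low_side)
  }
  if (anyNA(cat)) {
    unknown <- unique(drug[is.na(cat)])
    stop("drug(s) not in the risk map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  day_cat <- tapply(risk_factor(cat), day_ev$patient_id, max)
  out <- tibble::tibble(
    patient_id = names(day_cat),
    day_category = risk_levels[as.integer(day_cat)]
  )
  out <- dplyr::inner_join(fd, out, by = "patient_id")
  out <- dplyr::left_join(out, patients[, c("patient_id", "age_years")],
                          by = "patient_id")
  out$age_stratum <- age_stratum(out$age_years)
  out$stratum <- reporting_stratum(out$day_category, out$age_stratum)
  out$age_years <- NULL
  # restore input patient order
  out[match(patients$patient_id, out$patient_id), , drop = FALSE]
}
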