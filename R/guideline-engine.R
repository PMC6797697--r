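#' Load an antiemetic guideline rule set
#'
#' Rule sets are declarative YAML data: for each (emetic risk category,
#' age stratum) pair they list the admissible antiemetic class sets. A
#' regimen is concordant when it equals one admissible set exactly. The
#' package ships the ASCO 2006 and 2017 acute-phase recommendations; the
#' two editions differ only in the pediatric high-risk recommendation
#' (2017 adds the NK1RA) and in the low-risk recommendation (2017 admits a
#' 5HT3RA alone in addition to a steroid alone).
#'
#' @param version `"asco2006"` or `"asco2017"`, selecting a shipped rule
#'   set; ignored when `path` is given.
#' @param path optional path to a rule-set YAML with the same schema.
#' @return a list of class `guideline_ruleset` with elements `version` and
#'   `recommendation` (nested list category -> stratum -> list of character
#'   vectors).
#' @export
guideline_ruleset <- function(version = c("asco2006", "asco2017"), path = NULL) {
  if (is.null(path)) {
    version <- match.arg(version)
    path <- system.file("extdata", paste0("ruleset_", version, ".yaml"),
                        package = "cinvaudit")
  }
  r <- yaml::read_yaml(path)
  if (is.null(r$version) || is.null(r$recommendation)) {
    stop("rule set must have 'version' and 'recommendation'", call. = FALSE)
  }
  for (cat in risk_levels) {
    for (st in c("adult", "under18")) {
      sets <- r$recommendation[[cat]][[st]]
      if (is.null(sets)) {
        stop("rule set lacks an entry for (", cat, ", ", st, ")",
             call. = FALSE)
      }
      # yaml reads [] as list(); normalize each admissible set to character
      r$recommendation[[cat]][[st]] <- lapply(sets, function(s) {
        s <- as.character(unlist(s))
        bad <- setdiff(s, antiemetic_classes)
        if (length(bad) > 0) {
          stop("rule set names unknown class(es): ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        antiemetic_classes[antiemetic_classes %in% s]
      })
    }
  }
  structure(list(version = r$version, recommendation = r$recommendation),
            class = "guideline_ruleset")
}

#' Extract a patient's prophylactic antiemetic regimen
#'
#' Antiemetics administered on the same day as the first chemotherapy are
#' taken as prophylactic; administrations on any other day are ignored.
#' The regimen is the set (union, no multiplicity) of antiemetic classes
#' given that day.
#'
#' @param patient one-row data frame with `patient_id`.
#' @param events administration event table.
#' @param first_day integer, the patient's first parenteral chemotherapy
#'   day (from [select_cohort()] or [assign_first_day_risk()]).
#' @param map a `drug_map` from [load_drug_map()].
#' @return character vector of classes (possibly empty).
#' @export
extract_regimen <- function(patient, events, first_day, map = load_drug_map()) {
  ev <- events[events$patient_id == patient$patient_id &
                 events$event_class == "antiemetic" &
                 events$day_index == first_day, , drop = FALSE]
  if (nrow(ev) == 0) return(character(0))
  cls <- unlist(map$antiemetics[tolower(ev$drug_name)])
  unknown <- unique(ev$drug_name[!(tolower(ev$drug_name) %in%
                                     names(map$antiemetics))])
  if (length(unknown) > 0) {
    stop("antiemetic drug(s) not resolvable to a class: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  antiemetic_classes[antiemetic_classes %in% cls]
}

#' Evaluate one regimen against a guideline rule set
#'
#' A regimen is concordant if it equals one of the admissible class sets
#' for its (risk category, age stratum) cell. For a discordant regimen the
#' discordance is decomposed against the nearest admissible set (minimum
#' symmetric difference; ties broken toward the first listed set, which
#' for the 2017 low-risk cell is the 5HT3RA option): `overused` are
#' classes present but not recommended, `underused` are classes
#' recommended but absent.
#'
#' @param regimen character vector of antiemetic classes, or a regimen
#'   label string (see [regimen_label()]).
#' @param day_category emetic risk category of the treatment day.
#' @param stratum `"adult"` or `"under18"`.
#' @param ruleset a `guideline_ruleset`.
#' @return list with `concordant` (logical), `overused`, `underused`
#'   (character vectors, empty when concordant).
#' @export
#' @examples
#' rs <- guideline_ruleset("asco2017")
#' evaluate_concordance("5HT3RA", "low", "adult", rs)$concordant   # TRUE
#' evaluate_concordance("5HT3RA", "low", "adult",
#'                      guideline_ruleset("asco2006"))             # overuse
evaluate_concordance <- function(regimen, day_category, stratum, ruleset) {
  stopifnot(inherits(ruleset, "guideline_ruleset"),
            day_category %in% risk_levels,
            stratum %in% c("adult", "under18"))
  if (is.character(regimen) && length(regimen) == 1L &&
      !(regimen %in% antiemetic_classes)) {
    regimen <- parse_regimen(regimen)
  }
  regimen <- unique(regimen)
  bad <- setdiff(regimen, antiemetic_classes)
  if (length(bad) > 0) {
    stop("unknown antiemetic class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  admissible <- ruleset$recommendation[[day_category]][[stratum]]
  if (any(vapply(admissible, function(s) setequal(s, regimen), logical(1)))) {
    return(list(concordant = TRUE, overused = character(0),
                underused = character(0)))
  }
  symdiff <- vapply(admissible, function(s) {
    length(setdiff(regimen, s)) + length(setdiff(s, regimen))
  }, numeric(1))
  ref <- admissible[[which.min(symdiff)]]  # which.min takes first on ties
  list(
    concordant = FALSE,
    overused  = antiemetic_classes[antiemetic_classes %in%
                                     setdiff(regimen, ref)],
    underused = antiemetic_classes[antiemetic_classes %in%
                                     setdiff(ref, regimen)]
  )
}

#' Audit a whole cohort against one or more guideline rule sets
#'
#' Composes the pipeline per patient: first-treatment-day risk (highest
#' risk among same-day parenteral chemotherapy drugs), same-day
#' prophylactic regimen extraction, and concordance evaluation under each
#' rule set, with the overuse/underuse decomposition for discordant
#' regimens.
#'
#' @param patients patient table (must already pass [select_cohort()]).
#' @param events administration event table.
#' @param map a `drug_map`.
#' @param rulesets named list of `guideline_ruleset` objects; default both
#'   shipped ASCO editions.
#' @param bsa_formula BSA formula for the dose-per-m2 risk rules.
#' @return tibble with one row per patient: `patient_id`, `first_day`,
#'   `day_category`, `age_stratum`, `stratum`, `age_group`, `regimen`
#'   (canonical label), and per rule set `concordant_<v>`, `overused_<v>`,
#'   `underused_<v>` (labels, `""` when empty).
#' @export
evaluate_cohort <- function(patients, events, map = load_drug_map(),
                            rulesets = list(
                              asco2006 = guideline_ruleset("asco2006"),
                              asco2017 = guideline_ruleset("asco2017")),
                            bsa_formula = c("dubois", "mosteller")) {
  bsa_formula <- match.arg(bsa_formula)
  if (nrow(patients) == 0) {
    return(tibble::tibble(patient_id = character(0)))
  }
  risk <- assign_cohort_risk(patients, events, map, bsa_formula)

  # vectorised regimen extraction: antiemetic events on each patient's
  # first chemo day
  anti <- events[events$event_class == "antiemetic", , drop = FALSE]
  anti <- dplyr::inner_join(anti,
                            risk[, c("patient_id", "first_day")],
                            by = "patient_id")
  anti <- anti[anti$day_index == anti$first_day, , drop = FALSE]
  lower <- tolower(anti$drug_name)
  unknown <- unique(anti$drug_name[!(lower %in% names(map$antiemetics))])
  if (length(unknown) > 0) {
    stop("antiemetic drug(s) not resolvable to a class: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  anti$class <- unlist(map$antiemetics)[lower]
  reg <- tapply(anti$class, anti$patient_id,
                function(x) regimen_label(unique(x)))
  risk$regimen <- "none"
  hit <- match(names(reg), risk$patient_id)
  risk$regimen[hit] <- as.vector(reg)

  risk$age_group <- as.character(
    age_group(patients$age_years[match(risk$patient_id, patients$patient_id)]))

  # concordance per rule set: only 8 regimens x 4 categories x 2 strata
  # distinct cells, so evaluate the grid once and join
  for (v in names(rulesets)) {
    rs <- rulesets[[v]]
    cells <- unique(risk[, c("regimen", "day_category", "age_stratum")])
    ev <- lapply(seq_len(nrow(cells)), function(i) {
      evaluate_concordance(cells$regimen[i], cells$day_category[i],
                           cells$age_stratum[i], rs)
    })
    cells[[paste0("concordant_", v)]] <-
      vapply(ev, `[[`, logical(1), "concordant")
    cells[[paste0("overused_", v)]] <- vapply(ev, function(e) {
      if (length(e$overused) == 0) "" else paste(e$overused, collapse = "+")
    }, character(1))
    cells[[paste0("underused_", v)]] <- vapply(ev, function(e) {
      if (length(e$underused) == 0) "" else paste(e$underused, collapse = "+")
    }, character(1))
    risk <- dplyr::left_join(risk, cells,
                             by = c("regimen", "day_category", "age_stratum"))
  }
  tibble::as_tibble(risk)
}
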