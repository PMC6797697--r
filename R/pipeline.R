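#' Validate cohort tables
#'
#' Schema, type, domain and referential-integrity checks for the two
#' cohort tables, with row-numbered diagnostics (row 1 = first data row;
#' add 1 for the CSV header line). Missing height/weight is flagged (the
#' dose-per-m2 risk rules need them) but is not a schema violation.
#'
#' @param patients patient table or path to `patients.csv`.
#' @param events event table or path to `administrations.csv`.
#' @return tibble of violations: `table`, `row`, `column`, `problem`
#'   (zero rows when everything is well formed).
#' @export
validate_tables <- function(patients, events) {
  if (is.character(patients)) patients <- utils::read.csv(
    patients, stringsAsFactors = FALSE,
    colClasses = c(patient_id = "character"))
  if (is.character(events)) events <- utils::read.csv(
    events, stringsAsFactors = FALSE,
    colClasses = c(patient_id = "character"))
  v <- list()
  note <- function(table, row, column, problem) {
    v[[length(v) + 1]] <<- tibble::tibble(
      table = table, row = as.integer(row), column = column,
      problem = problem)
  }

  p_cols <- c("patient_id", "age_years", "sex", "disease_class",
              "height_cm", "weight_kg")
  e_cols <- c("patient_id", "day_index", "drug_name", "route", "dose_mg",
              "event_class")
  for (m in setdiff(p_cols, names(patients))) {
    note("patients", NA, m, "missing required column")
  }
  for (m in setdiff(e_cols, names(events))) {
    note("events", NA, m, "missing required column")
  }
  if (length(v) > 0) return(dplyr::bind_rows(v))

  dup <- which(duplicated(patients$patient_id))
  for (i in dup) note("patients", i, "patient_id", "duplicate patient_id")
  bad <- which(!(patients$sex %in% c("male", "female")))
  for (i in bad) note("patients", i, "sex",
                      "sex must be 'male' or 'female'")
  bad <- which(!(patients$disease_class %in%
                   c("solid", "hematologic", "brain")))
  for (i in bad) note("patients", i, "disease_class",
                      "unknown disease class")
  bad <- which(is.na(patients$age_years) | patients$age_years < 0 |
                 patients$age_years != floor(patients$age_years))
  for (i in bad) note("patients", i, "age_years",
                      "age must be a nonnegative integer")
  bad <- which(!is.na(patients$height_cm) & patients$height_cm <= 0)
  for (i in bad) note("patients", i, "height_cm",
                      "height must be positive")
  bad <- which(!is.na(patients$weight_kg) & patients$weight_kg <= 0)
  for (i in bad) note("patients", i, "weight_kg",
                      "weight must be positive")
  bad <- which(is.na(patients$height_cm) | is.na(patients$weight_kg))
  for (i in bad) note("patients", i, "height_cm/weight_kg",
                      "missing anthropometrics (flag): dose rules will fail")

  bad <- which(!(events$patient_id %in% patients$patient_id))
  for (i in bad) note("events", i, "patient_id",
                      paste0("unknown patient_id '", events$patient_id[i],
                             "'"))
  bad <- which(!(events$route %in% c("parenteral", "oral")))
  for (i in bad) note("events", i, "route",
                      "route must be 'parenteral' or 'oral'")
  bad <- which(!(events$event_class %in%
                   c("chemotherapy", "antiemetic", "other")))
  for (i in bad) note("events", i, "event_class", "unknown event class")
  bad <- which(!is.na(events$dose_mg) & events$dose_mg < 0)
  for (i in bad) note("events", i, "dose_mg", "dose must be nonnegative")
  bad <- which(is.na(events$day_index) |
                 events$day_index != floor(events$day_index))
  for (i in bad) note("events", i, "day_index",
                      "day_index must be an integer")

  if (length(v) == 0) {
    return(tibble::tibble(table = character(0), row = integer(0),
                          column = character(0), problem = character(0)))
  }
  dplyr::bind_rows(v)
}

default_pipeline_config <- function() {
  list(
    cohort = list(n_patients = 20000, seed = 1L),
    bsa_formula = "dubois",
    ci = "wilson",
    model_version = "asco2017",
    drug_map = NULL,      # NULL -> shipped default
    rulesets = c("asco2006", "asco2017")
  )
}

#' Run the full audit pipeline
#'
#' Orchestrates synth -> select -> classify -> audit -> report from a
#' single configuration (an R list or a YAML file with the same shape) and
#' one root seed. Writes all stage outputs as CSV/JSON into `out_dir` and
#' returns a run manifest (seed, configuration hash, per-stage row counts,
#' output paths). Per-stage progress and exclusion counts are logged to
#' stderr.
#'
#' Configuration sections: `cohort` (arguments of [cohort_config()]),
#' `bsa_formula` (`"dubois"`/`"mosteller"`), `ci` (`"wilson"`/`"wald"`),
#' `model_version`, `drug_map` (path or `NULL` for the shipped map),
#' `rulesets` (names of shipped rule sets).
#'
#' @param config list or path to a YAML file; omitted fields take
#'   defaults (20 000 patients, seed 1, Dubois, Wilson, 2017 outcome).
#' @param out_dir output directory, created if needed.
#' @param dry_run if `TRUE`, validate the configuration, drug map and rule
#'   sets, then return without generating or writing anything.
#' @param quiet suppress progress logging.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("cinvaudit_run"),
                         dry_run = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  log <- function(...) if (!quiet) message("[cinvaudit] ", ...)

  cc <- do.call(cohort_config, cfg$cohort)
  map <- load_drug_map(cfg$drug_map)
  rulesets <- lapply(cfg$rulesets, guideline_ruleset)
  names(rulesets) <- cfg$rulesets
  if (dry_run) {
    log("dry run: configuration, drug map and rule sets are valid; ",
        "nothing written")
    return(invisible(list(valid = TRUE, seed = cc$seed,
                          config_hash = rlang::hash(cfg))))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  log("synth: generating ", cc$n_patients, " patients (seed ", cc$seed, ")")
  cohort <- generate_cohort(cc)
  paths <- write_cohort(cohort$patients, cohort$events, out_dir)
  log("synth: ", nrow(cohort$patients), " patients, ",
      nrow(cohort$events), " administration events")

  sel <- select_cohort(cohort$patients, cohort$events)
  log("select: ", nrow(sel$patients), " patients retained (",
      nrow(cohort$patients) - nrow(sel$patients),
      " excluded: age >=30 or no parenteral chemotherapy)")

  risk <- assign_cohort_risk(sel$patients, sel$events, map,
                             cfg$bsa_formula)
  risk_path <- file.path(out_dir, "risk.csv")
  utils::write.csv(risk, risk_path, row.names = FALSE)
  log("classify: first-day risk assigned (",
      paste(names(table(risk$day_category)), table(risk$day_category),
            sep = "=", collapse = ", "), ")")

  results <- evaluate_cohort(sel$patients, sel$events, map, rulesets,
                             cfg$bsa_formula)
  conc_path <- file.path(out_dir, "concordance.csv")
  utils::write.csv(results, conc_path, row.names = FALSE)
  for (vn in names(rulesets)) {
    log("audit: ", vn, " concordant ",
        sum(results[[paste0("concordant_", vn)]]), "/", nrow(results))
  }

  summary_tab <- summarize_regimens(results, cfg$ci)
  rates <- dplyr::bind_rows(lapply(names(rulesets), function(vn) {
    r <- concordance_rates(results, vn, cfg$ci)
    r$version <- vn
    r
  }))
  misuse <- misuse_rates(results, cfg$model_version, "stratum")
  model <- fit_concordance_model(results, sel$patients, cfg$model_version)
  out_files <- c(
    paths,
    risk = risk_path, concordance = conc_path,
    summary = file.path(out_dir, "summary.csv"),
    rates = file.path(out_dir, "rates.csv"),
    misuse = file.path(out_dir, "misuse.csv"),
    model = file.path(out_dir, "model.json")
  )
  utils::write.csv(summary_tab, out_files[["summary"]], row.names = FALSE)
  utils::write.csv(rates, out_files[["rates"]], row.names = FALSE)
  utils::write.csv(misuse, out_files[["misuse"]], row.names = FALSE)
  jsonlite::write_json(
    list(version = model$version, n = model$n,
         terms = model$report),
    out_files[["model"]], auto_unbox = TRUE, digits = NA, na = "null")
  log("report: summary, rates, misuse and model written to ", out_dir)

  manifest <- list(
    seed = cc$seed,
    config_hash = rlang::hash(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rows = list(
      patients_generated = nrow(cohort$patients),
      events_generated = nrow(cohort$events),
      patients_selected = nrow(sel$patients),
      audited = nrow(results),
      summary_rows = nrow(summary_tab),
      rate_rows = nrow(rates),
      misuse_rows = nrow(misuse),
      model_terms = nrow(model$report)
    ),
    files = as.list(out_files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
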