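#' Emetic risk categories, antiemetic classes, and regimen labels
#'
#' The ASCO scheme classifies a chemotherapy drug by its probability of
#' causing emesis without prophylaxis: high (>90%), moderate (30-90%),
#' low (10-30%), minimal (<10%). Risk categories are totally ordered
#' (`minimal < low < moderate < high`); a treatment day's category is the
#' maximum over the drugs given that day. Prophylactic antiemetics are
#' tracked at the class level: NK1RA (neurokinin-1 receptor antagonists),
#' 5HT3RA (serotonin receptor antagonists), and steroids. A regimen is a
#' subset of those three classes (8 possible subsets, the empty set printed
#' as `"none"`).
#'
#' @name risk-categories
#' @keywords internal
NULL

#' @rdname risk-categories
#' @format `risk_levels` is a character vector of the four categories in
#'   increasing emetogenicity order.
#' @export
risk_levels <- c("minimal", "low", "moderate", "high")

#' @rdname risk-categories
#' @format `antiemetic_classes` is a character vector of the three tracked
#'   antiemetic classes in canonical display order.
#' @export
antiemetic_classes <- c("NK1RA", "5HT3RA", "steroid")

#' @rdname risk-categories
#' @format `cohort_strata` is a character vector of the five reporting
#'   strata (the high category is split at age 18).
#' @export
cohort_strata <- c("minimal", "low", "moderate", "high_adult", "high_under18")

# Seven age groups used throughout; reference level for modelling is 25-29.
age_group_labels <- c("0-2", "3-4", "5-9", "10-14", "15-19", "20-24", "25-29")
age_group_breaks <- c(0, 3, 5, 10, 15, 20, 25, 30)

#' Assign the seven-level age group
#'
#' Ages (integer years at first chemotherapy) are grouped as 0-2, 3-4, 5-9,
#' 10-14, 15-19, 20-24, 25-29.
#'
#' @param age_years integer vector of ages in completed years, 0-29.
#' @return factor with the seven age-group levels.
#' @export
age_group <- function(age_years) {
  stopifnot(is.numeric(age_years), all(age_years >= 0 & age_years <= 29))
  cut(age_years, breaks = age_group_breaks, labels = age_group_labels,
      right = FALSE)
}

#' Age stratum used by the guideline rule sets
#'
#' The pediatric/adult boundary is <18 versus >=18 years at the first
#' chemotherapy day; it is the only age stratification the rule sets use.
#'
#' @param age_years integer vector of ages in completed years.
#' @return character vector, `"under18"` or `"adult"`.
#' @export
age_stratum <- function(age_years) {
  ifelse(age_years < 18, "under18", "adult")
}

#' Canonical label for an antiemetic class set
#'
#' @param classes character vector, a subset of [antiemetic_classes]
#'   (duplicates allowed, ignored). The empty set maps to `"none"`.
#' @return single string, classes joined by `"+"` in canonical order.
#' @seealso [parse_regimen()]
#' @export
#' @examples
#' regimen_label(c("steroid", "5HT3RA"))  # "5HT3RA+steroid"
#' regimen_label(character(0))            # "none"
regimen_label <- function(classes) {
  classes <- unique(classes)
  bad <- setdiff(classes, antiemetic_classes)
  if (length(bad) > 0) {
    stop("unknown antiemetic class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(classes) == 0) return("none")
  paste(antiemetic_classes[antiemetic_classes %in% classes], collapse = "+")
}

#' Parse a regimen label back to a class set
#'
#' @param label single string as produced by [regimen_label()] (`"none"`
#'   or `"+"`-joined class names, any order).
#' @return character vector of classes in canonical order (length 0 for
#'   `"none"`).
#' @export
parse_regimen <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label %in% c("none", "None", "")) return(character(0))
  classes <- strsplit(label, "+", fixed = TRUE)[[1]]
  bad <- setdiff(classes, antiemetic_classes)
  if (length(bad) > 0) {
    stop("unknown antiemetic class(es) in regimen label '", label, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  antiemetic_classes[antiemetic_classes %in% classes]
}

#' All eight possible regimens
#'
#' @return character vector of the 8 canonical regimen labels, `"none"`
#'   first, then by increasing size.
#' @export
all_regimens <- function() {
  c("none", "NK1RA", "5HT3RA", "steroid",
    "NK1RA+5HT3RA", "NK1RA+steroid", "5HT3RA+steroid",
    "NK1RA+5HT3RA+steroid")
}

# internal: ordered factor for max-aggregation
risk_factor <- function(x) {
  bad <- setdiff(unique(x), risk_levels)
  if (length(bad) > 0) {
    stop("unknown risk category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = risk_levels, ordered = TRUE)
}

# internal: five-level reporting stratum from day category + age stratum
reporting_stratum <- function(day_category, stratum) {
  ifelse(day_category == "high",
         ifelse(stratum == "under18", "high_under18", "high_adult"),
         day_category)
}
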