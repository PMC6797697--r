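#' Binomial proportion confidence intervals
#'
#' `wilson_ci()` is the Wilson score interval (no continuity correction),
#' the package default: it behaves at the 0/1 boundaries (the lower limit
#' is exactly 0 when x = 0). `wald_ci()` is the normal-approximation
#' interval `p +- z*sqrt(p(1-p)/n)`, truncated to [0, 1], provided because
#' at the audit's stratum sizes it reproduces the shape of published
#' interval estimates such as "51.1 (49.5-52.6)".
#'
#' @param x number of successes (vectorised).
#' @param n number of trials.
#' @param conf confidence level, default 0.95.
#' @return tibble with columns `estimate`, `low`, `high` (proportions).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(all(x >= 0), all(n > 0), all(x <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  low <- pmax(centre - half, 0)
  high <- pmin(centre + half, 1)
  # the score interval's limits are exactly 0 / 1 at the boundaries;
  # guard against round-off in centre - half
  low[x == 0] <- 0
  high[x == n] <- 1
  tibble::tibble(estimate = p, low = low, high = high)
}

#' @rdname wilson_ci
#' @export
wald_ci <- function(x, n, conf = 0.95) {
  stopifnot(all(x >= 0), all(n > 0), all(x <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  half <- z * sqrt(p * (1 - p) / n)
  tibble::tibble(estimate = p, low = pmax(p - half, 0),
                 high = pmin(p + half, 1))
}

ci_fun <- function(method = c("wilson", "wald")) {
  switch(match.arg(method), wilson = wilson_ci, wald = wald_ci)
}

#' Per-stratum regimen frequency table
#'
#' Tabulates the audited cohort's prophylactic regimens within each of the
#' five reporting strata (minimal, low, moderate, high >=18 y, high <18 y),
#' with percentages and 95% binomial confidence intervals. All eight
#' possible regimens are reported per stratum (zero counts included), so
#' per-stratum percentages sum to 100.
#'
#' @param results audit results from [evaluate_cohort()].
#' @param ci `"wilson"` (default) or `"wald"`.
#' @param conf confidence level.
#' @return tibble: `stratum`, `regimen`, `count`, `n`, `percent`,
#'   `ci_low`, `ci_high` (percent scale).
#' @export
summarize_regimens <- function(results, ci = c("wilson", "wald"),
                               conf = 0.95) {
  if (is.null(results) || nrow(results) == 0) {
    stop("summarize_regimens requires a nonempty results table",
         call. = FALSE)
  }
  f <- ci_fun(ci)
  grid <- expand.grid(stratum = intersect(cohort_strata,
                                          unique(results$stratum)),
                      regimen = all_regimens(),
                      stringsAsFactors = FALSE)
  counts <- dplyr::count(results, .data$stratum, .data$regimen)
  out <- dplyr::left_join(grid, counts, by = c("stratum", "regimen"))
  out$n[is.na(out$n)] <- 0L
  names(out)[names(out) == "n"] <- "count"
  ns <- table(results$stratum)
  out$n <- as.integer(ns[out$stratum])
  iv <- f(out$count, out$n, conf)
  out$percent <- 100 * iv$estimate
  out$ci_low <- 100 * iv$low
  out$ci_high <- 100 * iv$high
  tibble::as_tibble(out[order(match(out$stratum, cohort_strata),
                              match(out$regimen, all_regimens())), ])
}

#' Per-stratum concordance rates
#'
#' Fraction of patients whose prophylactic regimen is concordant with the
#' selected guideline edition, by reporting stratum, with binomial CIs.
#' Counts are exact: `rate * n / 100` equals the integer number of
#' concordant patients.
#'
#' @param results audit results from [evaluate_cohort()].
#' @param version rule-set name; must match a `concordant_<version>`
#'   column of `results`.
#' @inheritParams summarize_regimens
#' @return tibble: `stratum`, `n`, `n_concordant`, `rate` (percent),
#'   `ci_low`, `ci_high`.
#' @export
concordance_rates <- function(results, version = "asco2017",
                              ci = c("wilson", "wald"), conf = 0.95) {
  col <- paste0("concordant_", version)
  if (is.null(results) || nrow(results) == 0) {
    stop("concordance_rates requires a nonempty results table",
         call. = FALSE)
  }
  if (!col %in% names(results)) {
    stop("results has no column '", col, "'", call. = FALSE)
  }
  f <- ci_fun(ci)
  agg <- dplyr::summarise(
    dplyr::group_by(results, .data$stratum),
    n = dplyr::n(),
    n_concordant = sum(.data[[col]]),
    .groups = "drop"
  )
  iv <- f(agg$n_concordant, agg$n, conf)
  agg$rate <- 100 * iv$estimate
  agg$ci_low <- 100 * iv$low
  agg$ci_high <- 100 * iv$high
  tibble::as_tibble(agg[order(match(agg$stratum, cohort_strata)), ])
}

#' Category-level concordance from a printed regimen-frequency table
#'
#' Desk-check computation: given per-stratum regimen frequencies (percent)
#' as printed in a published audit, classify each regimen row with the
#' rule engine and sum the percentages of the concordant rows. This
#' reproduces published category-level concordance rates exactly from the
#' printed table, with no patient-level data.
#'
#' @param freqs tibble with columns `stratum`, `regimen`, `percent`
#'   (default: [reference_regimen_frequencies()]).
#' @param ruleset a `guideline_ruleset`.
#' @return tibble: `stratum`, `concordance_pct`.
#' @export
#' @examples
#' concordance_from_frequencies(ruleset = guideline_ruleset("asco2017"))
concordance_from_frequencies <- function(freqs = reference_regimen_frequencies(),
                                         ruleset) {
  stopifnot(inherits(ruleset, "guideline_ruleset"),
            all(c("stratum", "regimen", "percent") %in% names(freqs)))
  cell <- function(stratum) {
    switch(stratum,
           high_adult = c("high", "adult"),
           high_under18 = c("high", "under18"),
           c(stratum, "adult"))  # rules for non-high categories are
                                 # stratum-invariant
  }
  conc <- vapply(seq_len(nrow(freqs)), function(i) {
    cs <- cell(freqs$stratum[i])
    evaluate_concordance(freqs$regimen[i], cs[1], cs[2], ruleset)$concordant
  }, logical(1))
  agg <- tapply(freqs$percent * conc, freqs$stratum, sum)
  tibble::tibble(stratum = names(agg),
                 concordance_pct = as.numeric(agg))[
    order(match(names(agg), cohort_strata)), ]
}

#' Overuse and underuse rates per antiemetic class
#'
#' For each group (reporting stratum or age group) and each antiemetic
#' class, the percentage of patients for whom that class was overused
#' (present but not recommended) or underused (recommended but absent)
#' under the selected guideline edition.
#'
#' @param results audit results from [evaluate_cohort()].
#' @param version rule-set name (column suffix in `results`).
#' @param grouping `"stratum"` (default) or `"age_group"`.
#' @return tibble: group column, `class`, `n`, `overuse_pct`,
#'   `underuse_pct`.
#' @export
misuse_rates <- function(results, version = "asco2017",
                         grouping = c("stratum", "age_group")) {
  grouping <- match.arg(grouping)
  over_col <- paste0("overused_", version)
  under_col <- paste0("underused_", version)
  if (!all(c(over_col, under_col) %in% names(results))) {
    stop("results lacks decomposition columns for version '", version, "'",
         call. = FALSE)
  }
  groups <- unique(results[[grouping]])
  if (grouping == "stratum") {
    groups <- intersect(cohort_strata, groups)
  } else {
    groups <- intersect(age_group_labels, groups)
  }
  rows <- list()
  for (g in groups) {
    sub <- results[results[[grouping]] == g, , drop = FALSE]
    for (cls in antiemetic_classes) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, class = cls, n = nrow(sub),
        overuse_pct = 100 * mean(grepl(cls, sub[[over_col]], fixed = TRUE)),
        underuse_pct = 100 * mean(grepl(cls, sub[[under_col]], fixed = TRUE))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  names(out)[1] <- grouping
  out
}

#' Logistic regression of guideline concordance on patient factors
#'
#' Fits a maximum-likelihood logistic model of concordance (1 = regimen
#' concordant with the selected guideline edition) on categorical patient
#' factors: age group (reference 25-29), sex (reference male), emetic risk
#' category (reference minimal) and disease class (reference solid
#' tumors). Reports odds ratios with Wald 95% CIs and two-sided p-values
#' at alpha = 0.05; an OR below 1 reads as a risk factor for discordance.
#'
#' @param results audit results from [evaluate_cohort()], or a model-ready
#'   data frame containing the covariate columns and a logical
#'   `concordant` column (e.g. from [simulate_concordance_data()]), in
#'   which case leave `patients` as `NULL`.
#' @param patients patient table supplying `sex` and `disease_class`
#'   (joined on `patient_id`); not needed for model-ready input.
#' @param version guideline edition defining the outcome (default 2017).
#' @param covariates subset of `c("age_group", "sex", "day_category",
#'   "disease")` to include.
#' @param conf confidence level for the Wald intervals.
#' @return object of class `concordance_model`: list with `report`
#'   (tibble: covariate, level, odds_ratio, ci_low, ci_high, p_value,
#'   reference), `fit` (the `glm` object), `version`, `n`.
#' @export
fit_concordance_model <- function(results, patients = NULL,
                                  version = "asco2017",
                                  covariates = c("age_group", "sex",
                                                 "day_category", "disease"),
                                  conf = 0.95) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  refs <- c(age_group = "25-29", sex = "male", day_category = "minimal",
            disease = "solid")
  if (is.null(patients)) {
    df <- as.data.frame(results)
    if (!"concordant" %in% names(df)) {
      col <- paste0("concordant_", version)
      if (!col %in% names(df)) {
        stop("input has neither 'concordant' nor '", col, "'", call. = FALSE)
      }
      df$concordant <- df[[col]]
    }
  } else {
    col <- paste0("concordant_", version)
    if (!col %in% names(results)) {
      stop("results has no column '", col, "'", call. = FALSE)
    }
    df <- dplyr::left_join(
      as.data.frame(results),
      as.data.frame(patients)[, c("patient_id", "sex", "disease_class")],
      by = "patient_id")
    df$disease <- df$disease_class
    df$concordant <- df[[col]]
  }
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov) > 0) {
    stop("missing covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if (sum(df$concordant) == 0 || sum(!df$concordant) == 0) {
    stop("model requires at least one concordant and one discordant ",
         "observation", call. = FALSE)
  }
  level_order <- list(
    age_group = age_group_labels,
    sex = c("male", "female"),
    day_category = c("minimal", "low", "moderate", "high"),
    disease = c("solid", "hematologic", "brain")
  )
  for (v in covariates) {
    f <- factor(as.character(df[[v]]),
                levels = intersect(level_order[[v]],
                                   unique(as.character(df[[v]]))))
    dropped <- setdiff(level_order[[v]], levels(f))
    present_expected <- setdiff(level_order[[v]],
                                unique(as.character(df[[v]])))
    if (length(present_expected) > 0) {
      warning("covariate '", v, "': empty level(s) dropped: ",
              paste(present_expected, collapse = ", "), call. = FALSE)
    }
    if (refs[[v]] %in% levels(f)) {
      f <- stats::relevel(f, ref = refs[[v]])
    }
    df[[v]] <- f
  }

  fml <- stats::as.formula(paste("concordant ~",
                                 paste(covariates, collapse = " + ")))
  warned <- character(0)
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sep <- any(grepl("fitted probabilities numerically 0 or 1", warned)) ||
    !fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  if (sep) {
    stop("logistic fit shows complete or quasi-complete separation; ",
         "odds ratios are not identified", call. = FALSE)
  }
  for (w in setdiff(warned,
                    warned[grepl("fitted probabilities", warned)])) {
    warning(w, call. = FALSE)
  }

  z <- stats::qnorm(1 - (1 - conf) / 2)
  sm <- summary(fit)$coefficients
  rows <- list()
  for (v in covariates) {
    lv <- levels(df[[v]])
    for (l in lv) {
      if (l == lv[1]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          covariate = v, level = l, odds_ratio = 1,
          ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
          reference = TRUE)
      } else {
        term <- paste0(v, l)
        b <- sm[term, "Estimate"]
        se <- sm[term, "Std. Error"]
        rows[[length(rows) + 1]] <- tibble::tibble(
          covariate = v, level = l, odds_ratio = exp(b),
          ci_low = exp(b - z * se), ci_high = exp(b + z * se),
          p_value = 2 * stats::pnorm(-abs(b / se)),
          reference = FALSE)
      }
    }
  }
  structure(list(report = dplyr::bind_rows(rows), fit = fit,
                 version = version, n = nrow(df)),
            class = "concordance_model")
}

#' @export
print.concordance_model <- function(x, ...) {
  cat("Logistic model of guideline concordance (", x$version, "), n = ",
      x$n, "\n", sep = "")
  r <- x$report
  or <- ifelse(r$reference, "1 (ref)",
               sprintf("%.2f (%.2f-%.2f)", r$odds_ratio, r$ci_low,
                       r$ci_high))
  p <- ifelse(r$reference, "",
              ifelse(r$p_value < 0.001, "<.001", sprintf("%.3f", r$p_value)))
  print(data.frame(covariate = r$covariate, level = r$level,
                   `OR (95% CI)` = or, p = p, check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}
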