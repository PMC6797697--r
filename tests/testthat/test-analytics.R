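test_that("Wilson and Wald intervals behave at boundaries and cover", {
  # zero successes: Wilson lower limit is exactly 0
  ci <- wilson_ci(0, 20)
  expect_identical(ci$low, 0)
  expect_gt(ci$high, 0)
  expect_equal(wilson_ci(2, 4)$estimate, 0.5)
  # Wald at large n reproduces the familiar p +- 1.96 sqrt(pq/n) shape
  w <- wald_ci(2110, 4130)
  expect_equal(w$estimate, 2110 / 4130, tolerance = 1e-12)
  expect_equal(w$high - w$low,
               2 * qnorm(0.975) * sqrt(w$estimate * (1 - w$estimate) / 4130),
               tolerance = 1e-12)

  # coverage of the Wilson interval at n = 100, by exact enumeration of
  # the binomial distribution (the deterministic limit of a simulation)
  ci <- wilson_ci(0:100, 100)
  for (p in c(0.05, 0.3, 0.5)) {
    hit <- ci$low <= p & p <= ci$high
    expect_gte(sum(dbinom(0:100, 100, p)[hit]), 0.93)
  }
})

test_that("regimen summary percentages are exact and sum to 100", {
  res <- tibble::tibble(
    patient_id = sprintf("P%d", 1:4),
    stratum = "moderate",
    regimen = c("5HT3RA", "5HT3RA", "none", "5HT3RA+steroid")
  )
  tab <- summarize_regimens(res)
  expect_identical(nrow(tab), 8L)  # all regimens, zero counts included
  expect_equal(tab$percent[tab$regimen == "5HT3RA"], 50)
  expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
  expect_identical(sum(tab$count), 4L)
  expect_true(all(tab$ci_low <= tab$percent & tab$percent <= tab$ci_high))
  expect_error(summarize_regimens(res[0, ]), "nonempty")
})

test_that("concordance rates use exact integer accounting", {
  res <- tibble::tibble(
    patient_id = sprintf("P%d", 1:10),
    stratum = rep(c("low", "minimal"), each = 5),
    concordant_asco2017 = c(rep(TRUE, 3), rep(FALSE, 2), rep(TRUE, 5))
  )
  r <- concordance_rates(res, "asco2017")
  expect_equal(r$rate[r$stratum == "low"], 60)
  expect_equal(r$rate[r$stratum == "minimal"], 100)
  expect_identical(r$rate * r$n / 100, as.numeric(r$n_concordant))
  expect_error(concordance_rates(res, "asco2006"), "asco2006")
})

test_that("misuse rates count per-class overuse and underuse", {
  # every high-adult patient on 5HT3RA alone: both other classes underused
  patients <- rbind(toy_patient("P1", 20), toy_patient("P2", 22),
                    toy_patient("P3", 8), toy_patient("P4", 3))
  events <- rbind(
    toy_event("P1", 0, "cisplatin"),
    toy_event("P1", 0, "ondansetron", class = "antiemetic"),
    toy_event("P2", 0, "cisplatin"),
    toy_event("P2", 0, "granisetron", class = "antiemetic"),
    # moderate with triple prophylaxis: NK1RA overused
    toy_event("P3", 0, "doxorubicin"),
    toy_event("P3", 0, "aprepitant", route = "oral", class = "antiemetic"),
    toy_event("P3", 0, "ondansetron", class = "antiemetic"),
    toy_event("P3", 0, "dexamethasone", class = "antiemetic"),
    # minimal with a 5HT3RA: overuse
    toy_event("P4", 0, "vincristine", dose = 1.2),
    toy_event("P4", 0, "ondansetron", class = "antiemetic")
  )
  res <- evaluate_cohort(patients, events)
  m <- misuse_rates(res, "asco2017", "stratum")
  ha <- m[m$stratum == "high_adult", ]
  expect_equal(ha$underuse_pct[ha$class == "steroid"], 100)
  expect_equal(ha$underuse_pct[ha$class == "NK1RA"], 100)
  expect_equal(ha$overuse_pct[ha$class == "5HT3RA"], 0)
  expect_equal(ha$underuse_pct[ha$class == "5HT3RA"], 0)
  mo <- m[m$stratum == "moderate", ]
  expect_equal(mo$overuse_pct[mo$class == "NK1RA"], 100)
  mi <- m[m$stratum == "minimal", ]
  expect_equal(mi$overuse_pct[mi$class == "5HT3RA"], 100)

  by_age <- misuse_rates(res, "asco2017", "age_group")
  expect_true(all(by_age$age_group %in% c("20-24", "5-9", "3-4")))
})

test_that("saturated 2x2 logistic fit equals the cross-product odds ratio", {
  a <- 40; b <- 60; c <- 25; d <- 75  # male conc/disc, female conc/disc
  df <- tibble::tibble(
    sex = rep(c("male", "male", "female", "female"),
              times = c(a, b, c, d)),
    concordant = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d))
  )
  fit <- fit_concordance_model(df, covariates = "sex")
  or <- fit$report$odds_ratio[fit$report$level == "female"]
  expect_equal(or, (c / d) / (a / b), tolerance = 1e-6)
})

test_that("logistic fit matches an independent Newton oracle", {
  dat <- simulate_concordance_data(
    200, coefs = list(age_group = c("0-2" = -0.5)), intercept = 0.2,
    seed = 31)
  fit <- fit_concordance_model(dat)
  # same design (reference levels 25-29 / male / minimal / solid)
  dat$age_group <- relevel(dat$age_group, "25-29")
  X <- model.matrix(concordant ~ age_group + sex + day_category + disease,
                    data = dat)
  beta <- logistic_newton(X, as.numeric(dat$concordant))
  expect_equal(unname(coef(fit$fit)), unname(beta), tolerance = 1e-6)
})

test_that("degenerate model inputs are diagnosed", {
  # complete separation
  df <- tibble::tibble(sex = rep(c("male", "female"), each = 30),
                       concordant = rep(c(TRUE, FALSE), each = 30))
  expect_error(fit_concordance_model(df, covariates = "sex"), "separation")
  # single-outcome input
  df2 <- tibble::tibble(sex = rep(c("male", "female"), 10),
                        concordant = TRUE)
  expect_error(fit_concordance_model(df2, covariates = "sex"),
               "at least one")
  # empty covariate level dropped with a warning
  dat <- simulate_concordance_data(500, seed = 8)
  dat <- dat[dat$disease != "brain", ]
  expect_warning(fit <- fit_concordance_model(dat), "empty level")
  expect_false("brain" %in% fit$report$level)
})

test_that("null generative model gives calibrated interval coverage", {
  covered <- matrix(NA, 30, 12)
  for (r in 1:30) {
    dat <- simulate_concordance_data(3000, intercept = -0.2, seed = 100 + r)
    fit <- fit_concordance_model(dat)
    rep_ <- fit$report[!fit$report$reference, ]
    covered[r, ] <- rep_$ci_low <= 1 & 1 <= rep_$ci_high
  }
  # per-term coverage of the true OR = 1 close to nominal 95%
  expect_true(all(colMeans(covered) >= 0.8))
  expect_gte(mean(covered), 0.9)
})

test_that("published frequency table reproduces printed category rates", {
  f <- reference_regimen_frequencies()
  expect_identical(nrow(f), 39L)
  r17 <- concordance_from_frequencies(f, guideline_ruleset("asco2017"))
  r06 <- concordance_from_frequencies(f, guideline_ruleset("asco2006"))
  get <- function(r, s) r$concordance_pct[r$stratum == s]
  expect_equal(get(r17, "low"), 57.9, tolerance = 1e-9)
  expect_equal(get(r06, "low"), 5.9, tolerance = 1e-9)
  expect_equal(get(r17, "minimal"), 51.6, tolerance = 1e-9)
})
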