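test_that("BSA formulas match closed-form oracle values", {
  # frozen high-precision evaluations of the closed forms
  expect_equal(compute_bsa(60, 60, "mosteller"), 1, tolerance = 1e-12)
  expect_equal(compute_bsa(180, 70, "dubois"), 1.88627738040808202,
               tolerance = 1e-9)
  expect_equal(compute_bsa(180, 70, "mosteller"), sqrt(3.5),
               tolerance = 1e-12)
  expect_equal(compute_bsa(120, 30, "dubois"), 0.98072954827418283,
               tolerance = 1e-9)
  # vectorised
  expect_equal(compute_bsa(c(60, 180), c(60, 70), "mosteller"),
               c(1, sqrt(3.5)), tolerance = 1e-12)
  expect_error(compute_bsa(0, 50), "positive")
  expect_error(compute_bsa(150, -1), "positive")
  expect_error(compute_bsa(NA_real_, 50), "positive")
})

test_that("Dubois and Mosteller agree over plausible anthropometrics", {
  # at growth-reference midpoints the two formulas agree to within 5%;
  # across the generator's full +-3 SD bands the worst case (infants)
  # stays within about 10%
  gr <- cinvaudit:::growth_reference
  d <- compute_bsa(gr$height_mean, gr$weight_mean, "dubois")
  m <- compute_bsa(gr$height_mean, gr$weight_mean, "mosteller")
  expect_lt(max(abs(m - d) / d), 0.05)

  co <- generate_cohort(cohort_config(20000, seed = 11))
  d <- compute_bsa(co$patients$height_cm, co$patients$weight_kg, "dubois")
  m <- compute_bsa(co$patients$height_cm, co$patients$weight_kg,
                   "mosteller")
  expect_lt(max(abs(m - d) / d), 0.11)
  expect_true(all(d > 0 & m > 0))
})

test_that("dose-rule drugs are classified with the guideline boundary sides", {
  map <- load_drug_map()
  bsa <- 1.25
  # cyclophosphamide: >= 1500 mg/m2 high, below moderate
  expect_identical(classify_drug("cyclophosphamide", 1500 * bsa, bsa, map),
                   "high")
  expect_identical(classify_drug("cyclophosphamide", 1499.99 * bsa, bsa, map),
                   "moderate")
  # cytarabine: > 1000 mg/m2 moderate, <= 1000 low
  expect_identical(classify_drug("cytarabine", 1000 * bsa, bsa, map), "low")
  expect_identical(classify_drug("cytarabine", 1000.01 * bsa, bsa, map),
                   "moderate")
  # fixed-category drugs ignore dose; lookup is case-insensitive
  expect_identical(classify_drug("vincristine", 2, bsa, map), "minimal")
  expect_identical(classify_drug("Vincristine", NA, bsa, map), "minimal")
  expect_identical(classify_drug("cisplatin", 1, bsa, map), "high")
  expect_error(classify_drug("notadrug", 10, bsa, map), "notadrug")
  expect_error(classify_drug("cytarabine", NA, bsa, map), "dose")
  expect_error(classify_drug("cyclophosphamide", 1000, NA, map), "bsa")
})

test_that("increasing a dose never decreases the assigned category", {
  map <- load_drug_map()
  ord <- function(cat) match(cat, risk_levels)
  for (drug in c("cyclophosphamide", "cytarabine")) {
    for (bsa in c(0.4, 1.0, 1.9)) {
      doses <- seq(10, 4000, by = 37) * bsa
      cats <- vapply(doses, function(d) classify_drug(drug, d, bsa, map),
                     character(1))
      expect_true(all(diff(ord(cats)) >= 0),
                  info = paste(drug, "bsa", bsa))
    }
  }
})

test_that("day-level risk is the maximum over same-day drugs", {
  expect_identical(aggregate_day_risk(c("moderate", "minimal")), "moderate")
  expect_identical(aggregate_day_risk("low"), "low")
  expect_identical(aggregate_day_risk(c("minimal", "low", "moderate",
                                        "high")), "high")
  expect_error(aggregate_day_risk(character(0)), "at least one")
  expect_error(aggregate_day_risk("severe"), "unknown")

  # order-invariant, idempotent, equals brute-force max over permutations
  set.seed(42)
  for (i in 1:25) {
    cats <- sample(risk_levels, sample(1:6, 1), replace = TRUE)
    agg <- aggregate_day_risk(cats)
    expect_identical(aggregate_day_risk(rev(cats)), agg)
    expect_identical(aggregate_day_risk(sample(cats)), agg)
    expect_identical(aggregate_day_risk(c(cats, agg)), agg)
    expect_identical(agg, risk_levels[max(match(cats, risk_levels))])
  }
})

test_that("first-treatment-day risk uses the first parenteral chemo day", {
  map <- load_drug_map()
  p <- toy_patient("A", 12)
  ev <- rbind(
    toy_event("A", 3, "etoposide"),
    toy_event("A", 10, "cisplatin")
  )
  r <- assign_first_day_risk(p, ev, map)
  expect_identical(r$first_day, 3L)
  expect_identical(r$day_category, "low")

  # oral chemo on the first day is excluded from risk scoring
  ev2 <- rbind(
    toy_event("A", 0, "vincristine"),
    toy_event("A", 0, "cisplatin", route = "oral")
  )
  r2 <- assign_first_day_risk(p, ev2, map)
  expect_identical(r2$day_category, "minimal")

  # age stratum boundary at 18
  r17 <- assign_first_day_risk(toy_patient("B", 17),
                               toy_event("B", 0, "cisplatin"), map)
  r18 <- assign_first_day_risk(toy_patient("C", 18),
                               toy_event("C", 0, "cisplatin"), map)
  expect_identical(r17$age_stratum, "under18")
  expect_identical(r17$stratum, "high_under18")
  expect_identical(r18$age_stratum, "adult")
  expect_identical(r18$stratum, "high_adult")

  expect_error(assign_first_day_risk(toy_patient("D", 5),
                                     toy_event("E", 0, "cisplatin"), map),
               "no parenteral chemotherapy")
})

test_that("vectorised cohort risk matches the per-patient path", {
  map <- load_drug_map()
  co <- generate_cohort(cohort_config(300, seed = 5))
  sel <- select_cohort(co$patients, co$events)
  vec <- assign_cohort_risk(sel$patients, sel$events, map)
  for (i in sample(nrow(sel$patients), 40)) {
    one <- assign_first_day_risk(sel$patients[i, ], sel$events, map)
    expect_identical(vec$day_category[i], one$day_category)
    expect_identical(vec$first_day[i], one$first_day)
    expect_identical(vec$stratum[i], one$stratum)
  }
})
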