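test_that("engine reproduces every published concordance mark exactly", {
  marks <- published_marks()
  rs06 <- guideline_ruleset("asco2006")
  rs17 <- guideline_ruleset("asco2017")
  for (i in seq_len(nrow(marks))) {
    cell <- stratum_cell(marks$stratum[i])
    got06 <- evaluate_concordance(marks$regimen[i], cell[1], cell[2],
                                  rs06)$concordant
    got17 <- evaluate_concordance(marks$regimen[i], cell[1], cell[2],
                                  rs17)$concordant
    expect_identical(got06, marks$c2006[i],
                     info = paste(marks$stratum[i], marks$regimen[i], "2006"))
    expect_identical(got17, marks$c2017[i],
                     info = paste(marks$stratum[i], marks$regimen[i], "2017"))
  }
  # rules for non-high categories do not depend on the age stratum
  for (i in which(!grepl("high", marks$stratum))) {
    for (rs in list(rs06, rs17)) {
      expect_identical(
        evaluate_concordance(marks$regimen[i], marks$stratum[i], "under18",
                             rs)$concordant,
        evaluate_concordance(marks$regimen[i], marks$stratum[i], "adult",
                             rs)$concordant)
    }
  }
})

test_that("2006 and 2017 rule sets differ exactly on pediatric high and low risk", {
  rs06 <- guideline_ruleset("asco2006")
  rs17 <- guideline_ruleset("asco2017")
  for (cat in risk_levels) {
    for (st in c("adult", "under18")) {
      same <- identical(rs06$recommendation[[cat]][[st]],
                        rs17$recommendation[[cat]][[st]])
      should_differ <- (cat == "high" && st == "under18") || cat == "low"
      expect_identical(!same, should_differ, info = paste(cat, st))
    }
  }
})

test_that("discordance decomposes into disjoint overuse and underuse", {
  rulesets <- list(guideline_ruleset("asco2006"), guideline_ruleset("asco2017"))
  for (rs in rulesets) {
    for (reg_label in all_regimens()) {
      reg <- parse_regimen(reg_label)
      for (cat in risk_levels) {
        for (st in c("adult", "under18")) {
          e <- evaluate_concordance(reg, cat, st, rs)
          expect_length(intersect(e$overused, e$underused), 0)
          expect_true(all(e$overused %in% reg))
          expect_length(intersect(e$underused, reg), 0)
          # concordant <=> empty decomposition
          expect_identical(e$concordant,
                           length(e$overused) + length(e$underused) == 0)
          # regimen = (reference set + overused) \ underused for some
          # admissible reference
          ref <- union(setdiff(reg, e$overused), e$underused)
          admissible <- rs$recommendation[[cat]][[st]]
          expect_true(any(vapply(admissible, setequal, logical(1), ref)),
                      info = paste(rs$version, reg_label, cat, st))
        }
      }
    }
  }
})

test_that("low-risk 2017 decomposition ties break toward the 5HT3RA option", {
  rs <- guideline_ruleset("asco2017")
  # {NK1RA} is distance 2 from both {5HT3RA} and {steroid}
  e <- evaluate_concordance("NK1RA", "low", "adult", rs)
  expect_false(e$concordant)
  expect_identical(e$overused, "NK1RA")
  expect_identical(e$underused, "5HT3RA")
  # {5HT3RA, steroid} is distance 1 from both; tie -> 5HT3RA reference,
  # so the steroid is the overused class
  e2 <- evaluate_concordance(c("5HT3RA", "steroid"), "low", "adult", rs)
  expect_identical(e2$overused, "steroid")
  expect_identical(e2$underused, character(0))
  # under 2006 the same regimen against {steroid} overuses the 5HT3RA
  e3 <- evaluate_concordance(c("5HT3RA", "steroid"), "low", "adult",
                             guideline_ruleset("asco2006"))
  expect_identical(e3$overused, "5HT3RA")
})

test_that("regimen extraction keeps only same-day antiemetics", {
  map <- load_drug_map()
  p <- toy_patient("A", 10)
  ev <- rbind(
    toy_event("A", 0, "cisplatin"),
    toy_event("A", 0, "aprepitant", route = "oral", dose = 125,
              class = "antiemetic"),
    toy_event("A", 0, "granisetron", dose = 3, class = "antiemetic"),
    toy_event("A", 0, "dexamethasone", dose = 8, class = "antiemetic"),
    toy_event("A", 1, "ondansetron", dose = 4, class = "antiemetic")
  )
  expect_identical(extract_regimen(p, ev, 0, map),
                   c("NK1RA", "5HT3RA", "steroid"))
  # next-day antiemetic alone is not prophylaxis
  ev2 <- rbind(toy_event("A", 0, "cisplatin"),
               toy_event("A", 1, "ondansetron", class = "antiemetic"))
  expect_identical(extract_regimen(p, ev2, 0, map), character(0))
  # duplicate class collapses to a set
  ev3 <- rbind(toy_event("A", 0, "ondansetron", class = "antiemetic"),
               toy_event("A", 0, "granisetron", class = "antiemetic"))
  expect_identical(extract_regimen(p, ev3, 0, map), "5HT3RA")
  ev4 <- rbind(toy_event("A", 0, "mysterydrug", class = "antiemetic"))
  expect_error(extract_regimen(p, ev4, 0, map), "mysterydrug")
})

test_that("cohort audit composes risk, regimen and both rule sets", {
  map <- load_drug_map()
  patients <- rbind(toy_patient("P1", 20), toy_patient("P2", 10),
                    toy_patient("P3", 25))
  events <- rbind(
    # P1: minimal risk, no prophylaxis -> concordant both editions
    toy_event("P1", 2, "vincristine", dose = 2),
    # P2: moderate risk + 5HT3RA/steroid -> concordant both editions
    toy_event("P2", 0, "doxorubicin", dose = 40),
    toy_event("P2", 0, "ondansetron", dose = 4, class = "antiemetic"),
    toy_event("P2", 0, "dexamethasone", dose = 8, class = "antiemetic"),
    # P3: adult high risk + triple prophylaxis -> concordant both editions
    toy_event("P3", 5, "cisplatin", dose = 120),
    toy_event("P3", 5, "aprepitant", route = "oral", dose = 125,
              class = "antiemetic"),
    toy_event("P3", 5, "granisetron", dose = 3, class = "antiemetic"),
    toy_event("P3", 5, "dexamethasone", dose = 12, class = "antiemetic")
  )
  res <- evaluate_cohort(patients, events, map)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$concordant_asco2006))
  expect_true(all(res$concordant_asco2017))
  expect_identical(res$stratum[res$patient_id == "P3"], "high_adult")
  expect_identical(res$regimen[res$patient_id == "P1"], "none")

  empty <- evaluate_cohort(patients[0, ], events[0, ], map)
  expect_identical(nrow(empty), 0L)
})
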