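# cinvaudit

Audit prophylactic antiemetic prescribing against the ASCO 2006 and 2017
antiemetic guidelines in administrative-claims-style inpatient records
for pediatric, adolescent and young-adult (AYA) oncology patients.

Chemotherapy-induced nausea and vomiting (CINV) is largely preventable
when prophylaxis matches the emetogenicity of the chemotherapy given.
`cinvaudit` is for pharmacoepidemiologists and health-services
researchers who want to measure guideline concordance from claims-style
drug administration tables: it classifies each first-treatment-day's
emetic risk, reads off the same-day antiemetic classes, labels the
regimen concordant or discordant under versioned declarative rule sets,
decomposes discordance into overuse/underuse per class, and models the
patient factors of concordance. Because national claims extracts are not
redistributable, the package includes a synthetic cohort generator that
emulates the structure of such data (defaults taken from a published
nationwide audit of 21 106 Japanese inpatients under 30), so the whole
pipeline is testable end to end with known ground truth.

## The method in brief

For patient *i* with first parenteral chemotherapy day *d(i)*:

* **Day risk**: each parenteral chemotherapy drug on *d(i)* gets an ASCO
  category in {minimal < low < moderate < high}; the day category is the
  maximum. Cyclophosphamide and cytarabine are dose-dependent: with
  BSA from the Dubois formula (0.007184 h^0.725 w^0.425),
  cyclophosphamide is high when dose/BSA ≥ 1500 mg/m² (else moderate),
  cytarabine is moderate when dose/BSA > 1000 mg/m² (else low).
* **Regimen**: R(i) ⊆ {NK1RA, 5HT3RA, steroid}, the classes administered
  on *d(i)* (same-day = prophylactic).
* **Concordance**: R(i) is concordant under guideline g iff
  R(i) ∈ A_g(category, age stratum), the admissible sets of the rule
  set (age stratum: <18 vs ≥18). Discordance decomposes against the
  nearest admissible set into overused = R \ A and underused = A \ R.
* **Reporting**: per-stratum regimen frequencies and concordance rates
  with Wilson (default) or Wald 95% binomial CIs, and a logistic model
  of concordance on age group, sex, risk category and disease class
  (references 25–29 y, male, minimal, solid; OR < 1 reads as a risk
  factor for discordance).

## Worked example

The `analysis/` scripts run the full workflow (simulate → classify →
audit → report) and write their tables under `results/`. A condensed
version:

```r
library(cinvaudit)

cfg    <- cohort_config(n_patients = 20000, seed = 20100701)
cohort <- generate_cohort(cfg)
sel    <- select_cohort(cohort$patients, cohort$events)
res    <- evaluate_cohort(sel$patients, sel$events)
concordance_rates(res, "asco2017")
```

```
# A tibble: 5 × 6
  stratum          n n_concordant  rate ci_low ci_high
  <chr>        <int>        <int> <dbl>  <dbl>   <dbl>
1 minimal       1364          730  53.5   50.9    56.2
2 low           5435         3151  58.0   56.7    59.3
3 moderate      6791         2165  31.9   30.8    33.0
4 high_adult    3032         1543  50.9   49.1    52.7
5 high_under18  3378          732  21.7   20.3    23.1
```

Because the generator's regimen weights default to the published
frequencies, these synthetic rates sit within sampling error of the
published category-level rates (51.6 / 57.9 / 32.1 / 51.1 / 21.5). Under
the 2006 rules the same cohort gives 5.6% in the low-risk stratum —
the 2017 revision, which newly admits a 5HT3RA alone for low-risk
chemotherapy, is what lifts that stratum to 58%. The discordance
decomposition shows the dominant driver is steroid underuse
(`misuse_rates(res)`: 53% of moderate-risk and 59% of pediatric
high-risk patients missing a recommended steroid), and the factor model
(`fit_concordance_model(res, sel$patients)`) yields OR < 1 for younger
age groups and for moderate/high risk categories.

The rule engine can also be applied directly to a printed
regimen-frequency table, with no patient-level data:

```r
concordance_from_frequencies(reference_regimen_frequencies(),
                             guideline_ruleset("asco2017"))
#> # A tibble: 5 × 2
#>   stratum      concordance_pct
#>   <chr>                  <dbl>
#> 1 minimal                 51.6
#> 2 low                     57.9
#> 3 moderate                32.1
#> 4 high_adult              51.1
#> 5 high_under18            21.5
```

## Layout

| Path | Contents |
| --- | --- |
| `R/` | cohort synthesis, emetogenicity classification, guideline rule engine, analytics, pipeline orchestration |
| `inst/extdata/` | drug risk / antiemetic class map (YAML), ASCO 2006/2017 rule sets (YAML), published regimen-frequency table (CSV) |
| `analysis/` | numbered driver scripts for the full workflow |
| `scripts/acceptance.R` | recomputes the published category-level rates |
| `vignettes/concordance-audit.Rmd` | methods: model, assumptions, design choices, limitations |
| `tests/testthat/` | unit, property and end-to-end statistical tests |
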