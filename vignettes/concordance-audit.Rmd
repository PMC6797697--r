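---
title: "Auditing antiemetic prophylaxis against ASCO guidelines in claims-style pediatric and AYA oncology data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing antiemetic prophylaxis against ASCO guidelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chemotherapy-induced nausea and vomiting (CINV) is largely preventable
when prophylactic antiemetics are matched to the emetogenicity of the
chemotherapy being given. Professional guidelines (here, the ASCO 2006
and 2017 editions) recommend a specific combination of antiemetic
*classes* — NK1 receptor antagonists (NK1RA), serotonin receptor
antagonists (5HT3RA), and steroids — for each emetic risk category of the
chemotherapy day. Whether prescribing practice actually follows those
recommendations can be audited from inpatient administrative claims:
drug administration records carry the drug, date, route and dose, which
is exactly what is needed to (i) score each chemotherapy day's emetic
risk and (ii) read off the same-day antiemetic classes.

`cinvaudit` implements that audit as a pipeline over two claims-style
tables (a demographics table and a dated administration table), together
with a synthetic cohort generator that emulates the structure of a
national inpatient claims database for patients under 30 years of age.
Real national claims extracts are not redistributable, so every stage is
developed and tested against synthetic cohorts whose marginals default
to a published nationwide audit of 21 106 Japanese inpatients (2010–2016);
the published regimen-frequency table itself is shipped as data and used
as a deterministic desk check of the rule engine.

## The audit procedure

For each patient the pipeline:

1. **Selects** patients under 30 years of age with at least one
   *parenteral* chemotherapy administration (oral-only chemotherapy is
   excluded), and finds the first parenteral chemotherapy day. Only this
   first treatment day is analysed; later cycles are ignored.
2. **Scores emetogenicity.** Each parenteral chemotherapy drug given on
   that day is assigned an ASCO risk category (high >90%, moderate
   30–90%, low 10–30%, minimal <10% emesis without prophylaxis) from an
   editable drug map. Two drugs are dose-dependent and are classified on
   the administered dose divided by body surface area:
   cyclophosphamide at or above 1500 mg/m² is high risk (below,
   moderate); cytarabine strictly above 1000 mg/m² is moderate (at or
   below, low). The boundary sides matter and are tested exactly. BSA
   uses the Dubois formula
   ($0.007184\,h^{0.725}\,w^{0.425}$, $h$ in cm, $w$ in kg) by default,
   with Mosteller ($\sqrt{hw/3600}$) selectable. The day's category is
   the **maximum** over its drugs under
   minimal < low < moderate < high.
3. **Extracts the prophylactic regimen**: the set of antiemetic classes
   administered on the same day as the first chemotherapy. Same-day
   administration is the operational definition of prophylaxis in claims
   data; antiemetics on other days are ignored. Classes beyond the three
   tracked ones are outside the regimen universe (8 subsets of
   {NK1RA, 5HT3RA, steroid}).
4. **Evaluates concordance** against declarative rule sets. A rule set
   maps (risk category, age stratum) to a list of admissible class sets;
   a regimen is concordant iff it equals one admissible set exactly.
   The age stratum boundary is <18 versus ≥18 years, the only age split
   the recommendations use.

The shipped rule sets encode: 2006 — high/adult
{NK1RA, 5HT3RA, steroid}; high/under-18 {5HT3RA, steroid}; moderate
{5HT3RA, steroid}; low {steroid}; minimal {} (no prophylaxis). 2017 is
identical except high/under-18 becomes the triple combination and low
risk admits *either* {5HT3RA} *or* {steroid}.

Discordant regimens are decomposed into **overused** (present, not
recommended) and **underused** (recommended, absent) classes. When a
category admits several sets (low risk, 2017), the decomposition is
computed against the admissible set at minimum symmetric difference from
the observed regimen, with ties broken toward the {5HT3RA} option — the
option prescribed far more often in practice, so the decomposition
attributes the smallest and most plausible deviation. This reference-set
rule is a package design choice: per-class over/underuse rates are
well-defined only once a reference is fixed, and no published convention
exists for multi-option recommendations.

### A note on the published low-risk aggregates

In the audit whose marginals we ship, both low-risk rows "5HT3RA alone"
(52.0%) and "steroid alone" (5.9%) are concordant under the 2017 rules,
so the 2017 low-risk concordance rate implied by the printed table is
57.9%; some summaries of that audit quote 52.0% instead. The engine
follows the printed per-row marks and reports the 57.9% aggregate; both
row-level and aggregate views are available from
`summarize_regimens()` and `concordance_rates()`.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of claims data, not a
disease process. Its defaults are the study conditions of the published
audit and are not meant to be tuned per run:

* **Sample size and demographics**: seven age groups with the published
  weights (11.8%, 6.7%, 11.5%, 12.0%, 14.7%, 16.6%, 26.6% for 0–2
  through 25–29), male fraction 0.534, disease classes solid /
  hematologic / brain.
* **Risk category** of the first treatment day drawn with the published
  split (31.6% high, 34.1% moderate, 27.5% low, 6.9% minimal); the
  chemotherapy drug and dose are then chosen to *realise* that category,
  including cyclophosphamide/cytarabine administrations whose dose per
  m² lands on the correct side of the thresholds (with a safety margin
  so milligram rounding cannot flip the category).
* **Disease is drawn conditionally on risk category** (high risk mostly
  solid tumors, low risk mostly hematologic, in the direction of the
  published cross-tabulation) so that the factor model's covariates are
  not degenerate.
* **Regimens** on the first treatment day are drawn per reporting
  stratum from the published regimen frequencies, so the implied
  per-stratum concordance rates of a large synthetic cohort converge to
  the published rates.
* **Anthropometrics** are age-banded normal draws around growth-chart
  midpoints (unisex to age 12, sex-shifted after), truncated at ±3 SD.
  Only BSA plausibility matters downstream; the generator never emits
  missing height/weight, though the readers accept and flag them.
* **Noise** exercising the selection logic: a second cycle 21 days later
  with an independent regimen draw (40%), an additional same-day
  minimal-risk drug (25%), same-day oral chemotherapy (10%), and
  unrelated administrations (5%). None of these can change the planted
  first-day category: extra drugs are minimal-risk, oral agents are
  excluded from scoring, and later cycles are ignored.

What the generator does **not** emulate: admission/discharge structure,
coding errors, protocol schedules, therapeutic (non-prophylactic)
steroid use in leukemia protocols, delayed-phase antiemetics, and any
outcome (emesis) process. Tests passing on synthetic cohorts therefore
demonstrate that the *audit machinery* is correct under known ground
truth, not that real prescribing data are clean; in particular the
generator plants regimens independently of the covariates, so the
synthetic factor model's odds ratios arise only from the marginal
structure and are not the published real-data odds ratios, which are
deliberately out of scope.

## Statistical reporting

* **Proportions** (regimen frequencies, concordance rates) carry 95%
  binomial CIs. The default is the Wilson score interval, which is
  well-behaved at 0 and 1 (lower limit exactly 0 at zero successes); the
  Wald interval is selectable and at these stratum sizes (1 451–7 188)
  reproduces the shape of the published intervals to within 0.1 point.
  The Wilson interval's exact coverage at n = 100 is ≥ 93.7% for
  p ∈ {0.05, 0.3, 0.5}, verified in the tests by binomial enumeration.
* **Factors of concordance** are estimated by maximum-likelihood
  logistic regression of the 2017-edition concordance indicator on age
  group, sex, risk category and disease class, all categorical, with
  reference levels 25–29 years, male, minimal risk and solid tumors.
  Concordance (not discordance) is the outcome, so an odds ratio below 1
  reads as a risk factor for discordance. Wald 95% CIs and two-sided
  p-values at α = 0.05 are reported; no multiple-testing correction is
  applied, matching the field's reporting convention for such audits.
  The sex reference level is a package choice (male) and configurable in
  the sense that the cross-product structure makes the other direction
  the reciprocal. Complete or quasi-complete separation is diagnosed
  explicitly (non-convergence, boundary fitted probabilities, or
  runaway coefficients) and raised as an error rather than reported as
  a silently divergent fit; empty covariate levels are dropped with a
  warning.

## Numerical and design choices

* Dates are integer day offsets, not calendar dates: the method only
  ever compares days for equality and ordering.
* Dose-per-m² values are used unrounded; determinism is preferred over
  emulating any unstated clinical rounding.
* Drug → category and drug → antiemetic-class maps are YAML data, not
  code, so a site can re-point the audit at another guideline edition;
  the class (steroid), not the molecule (dexamethasone), is matched,
  because claims data contain many steroid molecules.
* The Dubois and Mosteller formulas agree to within 5% at
  growth-reference midpoint anthropometrics, and to within about 10%
  across the generator's full ±3 SD bands (the worst cases are infant
  height–weight extremes); the package tests assert exactly these
  bounds rather than a blanket claim over physiologically impossible
  height–weight combinations.
* All randomness flows from explicit integer seeds; identical
  configurations produce byte-identical CSV output. Where replicated
  simulations are needed, replicate seeds are drawn from a single root
  seed via `sample.int` — consecutive integer seeds produce correlated
  Mersenne–Twister streams and are not independent replicates.

## Problem sizes used by the test suite

The package's statistical checks run at sizes chosen to make their
Monte-Carlo error small relative to the margins they assert: the
generator round-trip uses a 100 000-patient cohort (every
stratum × regimen cell within 3 binomial SEs of its planted weight);
logistic parameter recovery uses 100 replicates of n = 50 000 with a
planted age-0–2 odds ratio of 0.53 (CI coverage of the planted effect
≥ 93%, per-term |bias| of the log-OR below 0.05, null-term coverage
within 3 binomial SEs of nominal); the estimator is cross-checked
against an independent Newton–Raphson maximiser to 10⁻⁶ on small
cohorts and against the closed-form cross-product odds ratio on a
saturated 2×2.

## Known limitations

* The audit scores the acute phase only; delayed-phase prophylaxis is
  out of scope.
* Therapeutic steroids (leukemia protocols, brain-tumor symptom
  control) are indistinguishable from prophylaxis in claims data and are
  counted as prophylactic — a known source of apparent "concordance" in
  hematologic disease.
* The rule engine covers the ASCO 2006/2017 editions; other guideline
  families (POGO, ESMO, JSCO) would be additional YAML rule sets but are
  not shipped.
* Real-data odds ratios cannot be reproduced from synthetic cohorts;
  the regression machinery is validated by parameter recovery instead.
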