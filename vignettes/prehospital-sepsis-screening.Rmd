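---
title: "Methods: prehospital sepsis screening on synthetic EMS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prehospital sepsis screening on synthetic EMS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsiscreen)
```

## What this package models

Emergency medical services (EMS) document vital signs in up to two
assessment slots per contact, often incompletely, and almost never record
an explicit sepsis suspicion. Retrospectively, one can ask: had EMS staff
applied a screening instrument to the vitals they (could have) measured,
how well would each instrument have predicted a subsequent inpatient
sepsis diagnosis? `sepsiscreen` implements that analysis as a pipeline:

1. **synthetic cohort** — EMS case records plus linked inpatient outcomes;
2. **preprocessing** — plausibility filtering, slot resolution, a
   consciousness/GCS bridge, and a selectable missing-data strategy;
3. **scoring** — prehospital-adapted qSOFA, SIRS, MEWS and NEWS2 with
   fixed positivity thresholds (≥2, ≥2, ≥4, ≥5);
4. **evaluation** — confusion matrices, Se/Sp/PPV/NPV, likelihood ratios,
   dichotomous AUROC, Wilson intervals, McNemar and Pearson χ² tests;
5. **intersections** — the 16-cell partition of cases by flagging tools
   and the combined *any*/*all* rules;
6. **cohort statistics** — incidence, case fatality, documentation
   completeness, suspicion rates.

Everything is driven by a JSON configuration and is deterministic given a
seed.

## The screening instruments and their prehospital adaptation

The score tables ship as versioned JSON (`inst/extdata/score_tables.json`)
rather than code, and are validated at load: interval bounds must strictly
increase (disjointness), start at the plausibility range's lower bound
(coverage), award non-negative points, and sum to the instrument's stated
maximum (qSOFA 3, SIRS 3, MEWS 14, NEWS2 20).

Adaptations to the prehospital setting: SIRS drops the leukocyte count and
the paCO₂ arm; MEWS drops urine output; NEWS2 is used with its standard
oxygen-saturation scale only (the hypercapnic "scale 2" needs a clinical
designation EMS records do not carry). qSOFA's altered-mentation item is
scored from the GCS (< 15), falling back on the documented ACVPU category
(anything but "A") when the GCS is undocumented — whether the original
analysis used GCS or the consciousness item is unknowable from the
published material, so the GCS-first convention is ours.

Two numerical conventions avoid boundary ambiguity: all vitals are
quantized before lookup (integers; temperature to one decimal, half-up, so
38.05 °C → 38.1 and scores as "> 38.0") and report rounding is half-up at
the displayed precision (1 dp for percentages and likelihood ratios, 3 dp
for AUROC). A documented "C" (new confusion) scores 1 point in MEWS — the
instrument predates ACVPU, and we treat new confusion as abnormal
mentation on par with "responds to voice".

## Preprocessing decisions

**Plausibility ranges.** The published supplement defining the original
bounds is not available, so the defaults (temperature 25–45 °C,
respiratory rate 1–80, heart rate 10–280, systolic pressure 40–320 mmHg,
SpO₂ 40–100 %, GCS integer 3–15) are this package's own stand-ins: wide
enough to keep genuine extreme physiology, narrow enough to exclude
transcription errors. They are overridable and recorded in the run
manifest.

**Slot resolution.** A variable counts as documented if either assessment
slot carries a value. When both do, the first wins by default —
first-contact values are the screening-relevant ones; a `worst-of-both`
mode (higher NEWS2 component points, ties to the first slot) is available
for sensitivity analyses.

**GCS → ACVPU.** 15 → A, 13–14 → V, 9–12 → P, ≤ 8 → U. This crosswalk is a
known contested convention (there is no validated bijection); "C" is never
auto-derived. The cut-offs are configurable.

**Missing-data strategies.** Four single-imputation strategies (point
estimates are the analysis output, so no multiple imputation):

* `complete_case`: a tool's score is undefined whenever a required input
  is missing; such cases are excluded from that tool's evaluation and from
  the intersection analysis entirely.
* `missing_as_normal`: missing vitals are set to a zero-scoring normal
  table (rr 12, SpO₂ 98 %, no supplemental O₂, SBP 120 mmHg, HR 75,
  37.0 °C, GCS 15, "A"). Note rr = 12, not 16: MEWS awards a point for
  respiratory rates 15–20, so 16 would violate the defining invariant of
  this strategy — that substituted values contribute zero points in
  *every* instrument. This invariant is re-verified at every load.
* `hotdeck`: seeded stratified hot-deck — each missing value is drawn from
  documented donors in the same age band (18–44, 45–64, 65–79, 80+) ×
  staff stratum, blind to the outcome; an empty stratum falls back to the
  global donor pool with a warning. This is the default main-analysis
  strategy and is declared a stand-in for the original (unpublished)
  imputation, not a reproduction of it.
* `missing_as_worst`: missing vitals are set to values attaining every
  instrument's maximal row simultaneously (rr 40, SpO₂ 85 %, on O₂, SBP
  60, HR 140, 34.0 °C, GCS 3, "U").

The normal strategy can only lower scores relative to any other strategy
applied to the same case, so positivity sets are nested and, on a fixed
cohort, its sensitivities bound the others from below while its
specificities bound them from above. This dominance is asserted as a
property test on every run.

## The synthetic cohort: what it emulates and what it does not

There is no public dataset: the underlying EMS and claims records are
legally non-depositable. The generator therefore reproduces the
*statistical structure* the analysis depends on, with every default a
stated quantity of the studied cohort where one exists:

* **Scale and labels**: 4503 linked adult cases with an inpatient sepsis
  prevalence of 78/4503; myocardial infarction 2.6 % and stroke 2.7 %
  (non-exclusive labels, as in claims data). An `exact_counts` switch
  plants exactly the expected count instead of Bernoulli draws.
* **Documentation rates** per variable and staff type (e.g. temperature
  17.7 % for paramedics, 19.8 % for emergency physicians; consciousness
  86.9 % / 68.6 %), applied as the probability that at least one slot is
  documented. Documented cases carry both slots (55 %), the first only
  (30 %) or the second only (15 %) — a choice of ours, not a reproduction.
* **Joint documentation**: the seven indicators share a one-factor
  Gaussian copula. Independence would give ≈ 1.7 % of cases with all seven
  variables documented, far below the ≈ 8 % observed in practice; the
  default loading of 0.65 was chosen once, by numerical integration of the
  copula at the configured marginal rates, to land near that joint rate.
  The marginals are untouched by the loading.
* **Severity shifts**: septic cases' true vitals are drawn from truncated
  normal distributions with shifted means (rr +8/min, HR +25/min,
  temperature +1.5 °C, SBP −25 mmHg, SpO₂ −6 pp, GCS −3). The
  distributions themselves are not published anywhere; the generator's
  contract is distributional *recovery* (configured shifts re-estimable
  from its output within Monte-Carlo error), not clinical realism.
* **Missingness mechanism**: MCAR per variable × staff stratum by
  default; an optional MAR mode shifts documentation log-odds for septic
  cases, motivated by reports that documentation deficits concentrate in
  urgent cases. Only MCAR marginal rates are contractual.
* **Mortality**: hospital death is Bernoulli given the case's condition
  (sepsis 31.6 %, MI 12.5 %, stroke 10 %, otherwise 1.5 %); additional
  out-of-hospital deaths bring the 30-day marginal to its target (sepsis
  31.7 %, MI 13.4 %, stroke 11.8 %, otherwise 2 %), with the death day
  uniform on days 0–30. Only the two marginal case-fatality rates are
  contractual.
* **Suspicion**: paramedics never document a sepsis suspicion; emergency
  physicians do so at 5/3483.
* **Contamination**: 1 % of documented numeric values are replaced by
  values outside the plausibility ranges, with a replacement log.

A green test on this cohort therefore establishes that the *machinery* is
correct (scores, strategy dominance, partition conservation, interval
coverage, parameter recovery) — it does **not** establish that the
generator's joint distribution matches real EMS physiology, and absolute
accuracy values on synthetic cohorts should not be quoted as estimates for
real ones.

## Statistical choices

* **Confidence intervals**: Wilson score intervals throughout (the method
  behind the published intervals is unstated; Wilson reproduces the two
  printable worked examples we can check, and a Wald variant is available
  behind `ci_method = "wald"`). One published lower bound (0.02 % for
  5/3483) is not reproducible by Wilson (≈ 0.06 %) and is treated as an
  open question, with only the upper bound asserted.
* **AUROC of a dichotomous rule** is (Se+Sp)/2 — the two-segment
  trapezoid; this identity is asserted for every evaluated rule. Its
  interval is a Wald combination of the two binomial variances; the
  original interval method is unknown, so only the point estimate is
  compared.
* **McNemar** defaults to the uncorrected statistic (b−c)²/(b+c), matching
  the original analysis convention; the continuity-corrected variant
  (`correct = TRUE`, with |b−c|−1 clamped at zero before squaring) is the
  one that tracks the exact binomial sign test (within 0.0025 for
  b+c ≥ 25) and is used for that invariant.
* **Pearson χ²** is uncorrected, with Cramér's V as the effect size;
  Bonferroni adjustment is provided for sensitivity analyses
  (reject iff p ≤ α/m).
* **Degenerate cases are flagged, not silently zeroed**: PPV with no
  positives is `NA`, LR+ at perfect specificity is `Inf`, McNemar with no
  discordant pairs returns p = 1 with a degeneracy flag.

## Known limitations

* The hot-deck stand-in, plausibility bounds, GCS→ACVPU crosswalk and slot
  pattern probabilities are this package's conventions where the original
  material is unavailable; all are configurable and logged.
* One acceptance test is intentionally red: the build contract's
  reconstruction rule (tp = round(Se·78), tn = round(Sp·4425)) reproduces
  46 of the 48 published accuracy cells at printed precision, but is
  arithmetically unable to reproduce two (the NEWS2 positivity rate and
  the all-four-tools PPV; consistent integer counts exist but the stated
  rounding rule does not select them). The test asserts the rule
  faithfully and fails, rather than papering over the defect.
* Continuous-score ROC curves, DeLong AUROC intervals, multiple
  imputation, the claims-data ICD operationalization of sepsis and the
  record-linkage procedure are out of scope.
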