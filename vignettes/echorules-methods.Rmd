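---
title: "Methods: a rule-based engine for aortic stenosis screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rule-based engine for aortic stenosis screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echorules)
```

## The classification model

`echorules` classifies each transthoracic echo study on a seven-level
ordinal severity scale — none (0), mild (1), mild-to-moderate (1.5),
moderate (2), moderate-to-severe (2.5), severe (3), critical (3.5) — and
dichotomizes at rank 2.5 ("sAS", the severity band for which valve
replacement is guideline-recommended). Two evidence channels feed a strict
hierarchy:

* **Qualitative.** The reading echocardiographer's free-text conclusion is
  scanned with a severity lexicon. The central modeling assumption, carried
  through every downstream rule, is that the written interpretation is
  definitionally the true severity class: when text and numbers disagree,
  the text wins, and an explicit denial of stenosis is itself a qualitative
  classification of grade none (it pre-empts quantitative grading rather
  than merely silencing the text channel).
* **Quantitative.** Measurements are graded against per-parameter interval
  tables, consulted in the strict order aortic valve area (cm²), then mean
  transvalvular gradient (mmHg), then peak jet velocity (m/s). When a
  higher-priority parameter is recorded, lower-priority values never
  influence the grade. The tertiary velocity fallback is on by default but
  switchable (`use_peak_velocity`), since site conventions differ on
  whether velocity alone should grade a study.

Both grades are always computed and reported with a discordance flag and
matched text spans, because a screening engine deployed against clinical
data must be auditable classification by classification. Leaflet-restriction
and abnormal-gradient comments are extracted as cues only; they never map to
a grade, since no defensible severity mapping exists for them.

Prosthetic aortic valves produce gradients that are uninterpretable under
native-valve criteria, so studies carrying either a structured prosthetic
flag or a textual prosthesis mention are excluded before classification.
When one patient has several studies in the window, the latest study is
retained (ties broken by greatest study id). Latest-study selection is a
package design choice: a screening cohort should reflect each patient's most
recent valve state.

## Tunable parameters

### Threshold table

The shipped defaults (editable YAML, `extdata/thresholds.yaml`) follow the
contemporary guideline convention:

| parameter | none | mild | moderate | severe | critical |
|---|---|---|---|---|---|
| AVA (cm²) | > 2.0 | (1.5, 2.0] | (1.0, 1.5] | (0.6, 1.0] | ≤ 0.6 |
| mean gradient (mmHg) | < 10 | [10, 20) | [20, 40) | [40, 60) | ≥ 60 |
| peak velocity (m/s) | < 2.0 | [2.0, 3.0) | [3.0, 4.0) | [4.0, 5.0) | ≥ 5.0 |

Three deliberate conventions:

* **Boundary ties break toward severity** (AVA exactly 1.0 → severe;
  gradient exactly 40 → severe). A screening tool should err toward
  sensitivity: a false positive costs one chart review, a false negative
  costs a missed referral.
* **Normal-range intervals map to grade none.** Interval tables must be
  exhaustive over each parameter's range for the validator
  (`validate_thresholds()`, which enforces disjointness, exhaustiveness and
  monotonicity at load) to be meaningful, and for the synthetic generator
  to draw grade-consistent values for unaffected valves. The gradient cut
  at 10 mmHg is the conventional sclerosis/stenosis boundary.
* **Quantitative grading never emits half-grades.** The half-grades are
  reader vocabulary, not guideline intervals; they can only enter through
  the text channel. A consequence worth knowing: a half-grade truth backed
  only by numbers is not exactly recoverable, which is why the generator
  forces readable text for half-grade studies.

### Lexicon

The lexicon (`extdata/lexicon.yaml`) is a reconstruction for native-valve
transthoracic conclusions and is expected to be re-tuned per site; patterns,
grades, priorities and negation cues are all config. Design choices:

* **Negation** is NegEx-style: cues ("no", "not", "without", "absence of",
  "free of", "negative for", "rather than") scope forward over 6 tokens,
  terminated at sentence punctuation (`. ; :`). Simple forward scoping is
  auditable and adequate for the telegraphic style of echo conclusions.
* **Containment resolution before severity resolution.** "Moderate to
  severe aortic stenosis" textually contains "severe aortic stenosis";
  matches strictly contained in longer matches are suppressed first, then
  the most severe surviving non-negated mention wins. The most-severe rule
  (rather than last-mention or first-mention) again biases toward
  sensitivity when a conclusion cites both a historical and a current grade.
* **"Aortic sclerosis" is absent from the lexicon** so that sclerosis
  without stenosis can never create a false positive; "without stenosis"
  is caught by the negation machinery as an explicit denial.
* The abbreviation "AS" is matched case-sensitively (`(?-i:AS)`) so prose
  "as" never fires.

### Validation protocol

`sample_adjudication_strata()` draws up to `n_per_stratum` studies uniformly
without replacement from three strata — untreated sAS, AS below sAS, no AS
identified — under a recorded seed; patients who opted out of chart review
are dropped after the draw (no replacement), mirroring how an opt-out
registry interacts with a pre-registered convenience sample. Concordance is
binary (same side of the sAS boundary) or half-grade (|rank difference|
≤ 0.5: moderate vs moderate-to-severe concordant, moderate vs severe not).
An adjudication of "not specified" counts as moderate-or-less in binary mode
and is excluded from half-grade mode — assigning it a rank would fabricate
information. Note one logical asymmetry that is easy to get wrong:
half-grade concordance does *not* imply binary concordance for the single
half-step pair straddling the sAS boundary; the suite tests this exhaustively
over all 49 grade pairs.

Sensitivity and specificity define "positive" by the adjudicated grade
being sAS. The no-AS stratum is audited solely for missed sAS, so it
contributes true negatives and false negatives only. The shipped reference
cross-tabulation (600 studies; accessor `reference_adjudication()`) yields
sensitivity 190/190 = 100% and specificity 400/410 = 97.6%, or 200/210 =
95.2% when the denominator is restricted to the engine-flagged strata. Both
are reported: the choice of denominator is a convention, and neither
recomputes to the 95.4% sometimes quoted for engines of this design, a
discrepancy the package surfaces rather than hides. Within that fixture,
the per-stratum marginals are fixed audit data while the within-stratum
joint pairing is a synthetic completion consistent with them (documented in
the accessor); every reported accuracy quantity depends only on the
marginals.

### Disparity analyses

Treatment status is AVR on or before a cutoff date (default 2024-06-10);
records flagged `carried_forward` (patients whose replacement fell in the
window but whose index echo preceded it) are accepted as pre-labelled input
and counted as treated, never reconstructed. Univariate comparisons use
Welch's t for continuous variables and a chi-square test without continuity
correction on the full contingency table, with Fisher's exact fallback when
any expected cell is below 5 — standard table-one conventions matching the
mean ± SD / n (%) display. The multivariable model for receipt of AVR is a
logistic fit by IRLS (`stats::glm`, tolerance 1e-10, max 100 iterations)
with Wald 95% intervals; references are female sex, White race,
Non-Hispanic ethnicity, Private insurance (configurable), "Unknown" is
modeled as a level rather than dropped, age enters linearly in years, and
the SDoH-stratified repeat adds the Healthy Places Index *percentile*
(higher = healthier neighbourhood), not the raw score. Constant covariates
are dropped with a message; extreme coefficients (>15 in absolute value) or
standard errors (>100) flag the fit as non-converged with a
separation diagnostic instead of returning silently absurd odds ratios.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces report text rendered from templates the shipped
lexicon can read (severity phrases, denials, prosthetic mentions, plus a
configurable fraction of deliberately out-of-lexicon templates that force
the quantitative-fallback path), measurements drawn from the open interior
of each grade's threshold interval (one representation step from every
boundary, so boundary tie-breaking is tested by dedicated fixtures and
never by chance), per-parameter missingness, prosthetic studies detectable
by at least one channel, opt-outs, missing SDoH, and treatment assigned to
true-sAS patients by a logistic model on age, sex, insurance and HPI.

Defaults were chosen once to echo the marginal structure of a large
single-center screening cohort: grade mixture (58.3% mild, 9.7%
mild-to-moderate, 20.8% moderate, 4.95% moderate-to-severe, 6.1% severe,
0.1% critical among gradeable studies), 45% missing SDoH, ages
Normal(78, 12) truncated at 18, demographic and insurance marginals from the
same setting, and treatment-model odds ratios echoing reported disparities
(0.96 per year of age, 1.52 for men, 0.48 Medicare, 0.24 HMO, 3.48 Medicare
Advantage, 0.53 per unit HPI percentile). Text is present for 85% of
studies and text/number discordance is planted at 10% by default.

The generator does **not** emulate: realistic clinical prose (templates are
short and regular, so lexicon recall is 100% by construction for in-lexicon
templates — a passing extraction suite certifies the machinery, not
real-world recall), joint dependence between demographics and severity,
comorbidity-driven treatment decisions, within-patient longitudinal series,
or echo physics linking AVA, gradient and velocity (each present parameter
is drawn independently from the same grade's interval). Consequently,
perfect recovery on clean synthetic cohorts demonstrates internal
consistency of the rules, not field performance on hospital text.

## Numerical and degenerate-input choices

* All randomness (sampling, generation, adjudication noise) flows through
  explicit integer seeds; caller RNG state is saved and restored.
* Stratified draws are taken from id-sorted strata, so results are
  invariant to input row order.
* Empty strata, empty cohorts, all-constant variables and zero
  denominators return absent values (`NA`) or diagnostics, never errors;
  truly contradictory inputs (modality without a date, out-of-range
  measurements, unknown enum literals) fail validation at load with
  row-level messages.
* Interval membership is evaluated with explicit open/closed bounds per
  interval — no floating-point epsilon games; the boundary convention is
  bit-exact and tested at every cut value.
* Measurements are rounded to their representation step (0.01 cm², 0.1
  mmHg, 0.01 m/s) at generation.

## Problem sizes

The test suite exercises cohorts of 200–10,000 patients (10,000 for grade-
mixture calibration, 5,000–6,000 for end-to-end recovery and disparity
recovery, smaller for mechanics) and 200-replicate simulations at n = 2,000
for logistic parameter recovery and null coverage; these sizes give
binomial/Monte-Carlo error comfortably inside the asserted 3-SD bands while
keeping the full suite around three minutes. `scripts/acceptance.R` re-runs
the headline computations at the same sizes in about a minute.

## Known limitations

* The lexicon is a reconstruction, tuned to its template corpus;
  site-specific phrasing (abbreviated conclusions, section headers,
  non-English fragments) will require lexicon edits, which is why it ships
  as config.
* Low-flow/low-gradient phenotypes, dimensionless index, stress echo and
  pressure-recovery adjustment are out of scope; the quantitative channel
  is deliberately the plain guideline table.
* Prosthetic-valve studies are excluded, not graded; prosthetic dysfunction
  needs different criteria entirely.
* The disparity models adjust for demographics, insurance and neighbourhood
  SDoH only; clinical comorbidities are not modeled, so estimates are
  associations, not causal effects.
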