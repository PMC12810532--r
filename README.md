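# echorules

Population-level identification and grading of aortic stenosis (AS) from
routine echocardiography data, with the validation protocol and
treatment-disparity analyses that belong with such a screening engine.

## The problem

Severe aortic stenosis is lethal when untreated, yet a large fraction of
patients whose echocardiogram already documents it never reach valve
replacement. Health systems hold the evidence in two places: the reading
echocardiographer's free-text conclusion, and the quantitative measures
recorded alongside it (calculated aortic valve area, mean transvalvular
gradient, peak jet velocity). `echorules` is for clinical data scientists and
quality-improvement teams who want a transparent, auditable, fully rule-based
engine over exactly those inputs — no machine learning, every classification
traceable to a matched phrase or a guideline cut-point.

## The engine

Each transthoracic study is classified on the ordinal scale
none < mild < mild-to-moderate < moderate < moderate-to-severe < severe <
critical (ranks 0 … 3.5; "sAS" = rank ≥ 2.5, i.e. moderate-to-severe or
worse) by a strict hierarchy:

1. **Qualitative channel.** A pattern lexicon with NegEx-style forward
   negation scoping extracts severity mentions (including half-grades),
   leaflet-restriction and abnormal-gradient cues, and prosthetic-valve
   mentions. An explicit denial ("no aortic stenosis") classifies as grade
   none; "aortic sclerosis" alone never produces AS.
2. **Quantitative channel.** Measurements are graded against guideline
   interval tables — AVA ≤ 1.0 cm² severe (≤ 0.6 critical), mean gradient
   ≥ 40 mmHg severe (≥ 60 critical), peak velocity ≥ 4 m/s severe — with a
   strict AVA → mean-gradient → peak-velocity fallback and boundary ties
   resolved toward the more severe grade.
3. **Hierarchy.** The written interpretation, when present, is
   definitionally the true severity class; the quantitative grade is final
   only when the text carries no AS signal. Both grades and a discordance
   flag are always emitted. Prosthetic-valve studies are excluded up front.

Around the engine the package provides the audit protocol (stratified
adjudication sampling; binary and half-grade concordance;
sensitivity/specificity with "positive" = adjudicated sAS), treatment-status
assignment at a follow-up cutoff, table-one univariate comparisons, IRLS
logistic models with Wald intervals for receipt of valve replacement (with
an SDoH-stratified repeat using the Healthy Places Index percentile), and a
fully labelled synthetic-cohort generator so the whole pipeline runs without
protected health information.

## Worked example

```r
library(echorules)

lex <- default_lexicon()
thr <- default_thresholds()

classify_study(list(study_id = "e1",
                    report_text = "Severe aortic stenosis.",
                    ava_cm2 = 1.3),
               lexicon = lex, thresholds = thr)
#>   study_id final_grade      source qualitative_grade quantitative_grade
#> 1       e1      severe qualitative            severe           moderate
#>   quantitative_parameter discordant is_sas leaflet_restriction
#> 1                ava_cm2       TRUE   TRUE               FALSE
#>   abnormal_gradient_comment
#> 1                     FALSE
```

The AVA of 1.3 cm² grades as moderate, but the attending wrote "severe", so
the final grade is severe with `source = "qualitative"` and the discordance
surfaced. On the shipped reference adjudication cross-tabulation (600
audited studies, 200 per stratum):

```r
pairs <- reference_adjudication()
confusion_metrics(pairs[pairs$stratum != "no_as", ],
                  pairs[pairs$stratum == "no_as", ])
#> sAS confusion summary (positive = adjudicated sAS)
#>   tp=190 fp=10 tn=400 fn=0
#>   sensitivity = 100.0%
#>   specificity = 97.6%
```

All 190 adjudicated-sAS studies were engine-flagged (no false negatives);
the 10 errors are engine overestimates — 5% of the flagged-sAS stratum.
Restricting the denominator to the two engine-flagged strata gives
specificity 200/210 = 95.2%; both denominators are reported because the
choice is a convention, not arithmetic.

A full synthetic end-to-end run:

```r
sim <- generate_cohort(generator_config(n_patients = 1000, seed = 1))
dir_in <- tempfile(); dir_out <- tempfile()
write_cohort(sim$cohort, dir_in, "csv")
res <- run_pipeline(dir_in, dir_out, format = "csv")
res$counts
```

A thin command-line wrapper with `simulate` / `extract` / `grade` /
`classify` / `validate` / `run` subcommands is in
`inst/cli/echorules.R`.

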