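---
title: "The PreMO risk indicator and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The PreMO risk indicator and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premor)
library(dplyr)
```

## The problem

Myopia that starts early progresses further, and each additional dioptre
of adult myopia raises the lifetime risk of sight-threatening pathology.
Children who are still emmetropic but on a myopic trajectory —
"pre-myopes" — can be identified from measurements an optometrist
already collects: cycloplegic spherical equivalent refraction (SER, in
dioptres), axial length (AL, in mm) and how many of the child's parents
are myopic. The PreMO (Predicting Myopia Onset and progression) risk
indicator turns these into a simple age-banded point score so that
behavioural advice and, where justified, prophylactic interventions can
be targeted at the children most likely to become myopic.

`premor` implements the indicator and, just as importantly, the
machinery used to validate it against longitudinal cohorts: ROC
analysis, Youden-optimal cut-offs, sensitivity/specificity/false
positive rate, bootstrap AUC intervals, and rank correlation between
the baseline score and the refraction the child ends up with at age 15
or older.

## The score

Two age bands are supported, reflecting the ages at which the
underlying point tables were derived:

* **6–8 years** (`age_6_8`, ages in [6, 9)): parental myopia scores
  0/2/3 for 0/1/2 myopic parents; SER scores 0 above +1.00 D, 2 from
  +0.75 to +1.00 D, 3 below +0.75 D; AL scores 0 below 22.94 mm, then
  1, 2 and 3 points from 22.94, 23.12 and 23.19 mm. Totals run 0–9.
* **9–10 years** (`age_9_10`, ages in [9, 11)): parental myopia scores
  0/1/2; SER scores 0 above +0.875 D, 1 from +0.375 to +0.875 D, 2
  below +0.375 D; AL scores 0 below 23.33 mm, then 1 and 2 points from
  23.33 and 23.62 mm. Totals run 0–6.

Totals map to categories: 0 little/no risk, 1–3 low, 4–6 moderate, 7–9
high, each with a predicted outcome ("likely to be myopic by 13 years
of age", and so on). Because the 9–10-year table tops out at 6, the
high-risk bin is unreachable in that band; we apply the bins unchanged
and treat this as a property of the published tables rather than
remapping them (`premo_risk_categories()` documents the bins; the test
suite asserts the unreachability explicitly).

### Interval conventions

The published SER bands are printed as open outer bands with a closed
middle band ("+0.75 to +1.00 D"); taking the middle band as closed at
both ends makes the three bands contiguous, so every dioptre value
scores exactly one way. The printed AL bands leave 0.01 mm gaps
(22.94–23.11 then 23.12–23.18) because the source values were reported
to 0.01 mm; we use half-open intervals anchored at the lower printed
bound of each higher band, which covers the whole real line without
overlap. A value such as 23.115 mm therefore scores 1 point. No input
rounding is performed anywhere — measurements are scored at whatever
precision they are supplied.

### Eye selection

Where both eyes are measured, the **least hyperopic / most emmetropic
eye** — the algebraically smaller SER — supplies both SER and AL (the
two measurements travel together; mixing eyes would pair a refraction
with the wrong globe length). An exact SER tie selects the right eye:
an arbitrary but deterministic and documented choice. Cohorts that
record only between-eye means use `eye_policy = "mean"`.

Children must be non-myopic at baseline (selected SER > −0.50 D,
myopia being SER ≤ −0.50 D throughout); a pre-myopia score for an
already-myopic child is meaningless and raises an error. Missing
parental history is likewise an error by default; the explicit
`assume_no_parental_myopia = TRUE` override scores it as zero and says
so in a message, because silently under-scoring heredity would bias
the indicator downward.

## Outcome labelling

The refractive outcome is assessed at age 15 or older: SER ≤ −0.50 D
is myopic, above it non-myopic. Two edge rules matter in longitudinal
clinic data:

* a child with documented myopia **before** 15 and no later record is
  assumed to have remained myopic (`carried_forward_onset`), since
  childhood-onset myopia does not spontaneously reverse;
* a **non-myopic** refraction before 15 resolves nothing — the child
  may still become myopic — and such records are rejected as
  unresolved rather than guessed at.

Ages are compared with 15 exactly, no rounding. An explicit
myopic/non-myopic column may confirm, but never override, a label
derived from a measured SER; contradictions are row errors. Records
whose outcome is label-only (no measured SER at ≥ 15) are kept for
classification but flagged ineligible for the rank-correlation
analysis, which needs the actual outcome refraction.

## The validation pipeline

`roc_curve()` sweeps every distinct value of the chosen feature plus
sentinel thresholds, so the curve always runs from (0, 0) to (1, 1),
and integrates the area under the (FPR, sensitivity) polygon by the
trapezoidal rule. This estimator equals the Mann–Whitney probability
that a random future myope outranks a random future non-myope, with
ties half-weighted — an identity the test suite verifies by full
pairwise enumeration on a thousand random cohorts.

The optimal cut-off maximises Youden's *J* = sensitivity +
specificity − 1. Ties are broken toward the **more sensitive**
threshold: in a screening context a missed future myope costs more
than a false alarm. For score- and AL-type predictors (positive call
at or above the cut-off) that is the lowest tied threshold; for
SER-type predictors (positive call below the cut-off) it is the
highest. Tied *J* values are recognised with a tolerance of 1e-9,
since the values being compared are ratios of small integer counts and
exact float equality would let representation noise pick the winner.

Positive-call directions are fixed per predictor — PreMO total ≥ t,
AL ≥ t, SER < t — matching how each cut-off is used clinically.

`auc_ci()` gives a percentile bootstrap interval (default 2000
resamples, seed mandatory) with resampling stratified by outcome, so
every resample contains both classes; a redraw guard for degenerate
resamples exists but is unreachable under stratification. The original
validation analyses were run in commercial statistics software whose
CI method is not stated; this interval is the package's own and is not
expected to match other software's analytic intervals digit for digit.
Its empirical coverage is itself tested: across 200 simulated cohorts
with a known true AUC of 0.85 (binormal scores, 250 cases and 250
controls each), the 95% interval covers the truth at close to the
nominal rate.

`spearman_score_ser()` is the rank correlation (average ranks for
ties) between the baseline total and the outcome SER, computed over
the records with a measured outcome refraction at ≥ 15 years.
Rounding to two decimals happens only when a report is rendered
(`format_validation_report()`); every comparison and stored value uses
full precision.

## Synthetic cohorts

No child-level data from the original validation cohorts are
available, so the package ships two substitutes.

**Fixture cohorts** (`premo_fixture()`, `fixture_from_confusion()`,
`fixture_singular()`) reconstruct cohorts exactly from published
contingency counts: for each reported row we emit precisely the right
number of future myopes and non-myopes whose *observations* — SER, AL
and parental history, never injected totals — score on the required
side of the cut-off. Component values are mid-band constants
(`premo_fixture_values()`), so the fixtures are robust to the interval
conventions above. Re-scoring a fixture through the full pipeline
reproduces the published sensitivity, specificity, FPR and incidence
cell by cell; scores on each side of the cut-off are spread
deterministically over the available totals so the ROC sweep is
non-degenerate.

**Generated cohorts** (`generate_cohort()`) draw from an explicit
generative model: baseline (SER, AL) bivariate normal with a negative
correlation (longer eyes are less hyperopic), truncated to non-myopic
baselines by rejection; multinomial parental myopia; per-eye records
in which the least hyperopic eye carries the drawn values and the
fellow eye is slightly more hyperopic and shorter, so eye selection
recovers the latent distribution exactly; and myopia by 15 as a
Bernoulli draw with probability `plogis(onset_intercept + onset_slope
× total)`. Outcome SER is drawn below −0.50 D for myopes with a
magnitude that grows with the score, and above it otherwise, with
Gaussian noise. Each call uses one stream seeded from `spec$seed` and
leaves the session's RNG untouched.

Three presets ship as YAML files (`premo_preset()`): `uk_6_8` (UK-like
population cohort), `hk_6_8` and `hk_9_10` (Hong-Kong-like clinic
cohorts). No baseline distribution parameters were published for the
real cohorts, so the presets state assumptions a paediatric-optometry
reader would recognise as plausible: mean baseline SER of +1.10 D (UK)
versus +0.90/+0.70 D (HK), axial lengths of 22.7 versus 23.1/23.4 mm,
SD ~0.6 D and ~0.7 mm, SER–AL correlation −0.45, and more parental
myopia in the HK presets. Each preset's `onset_intercept` was
calibrated once, by root-finding on the expected incidence under the
preset's own score distribution, to the reported incidences — 58%
(UK 6–8), 94% (HK 6–8) and 76% (HK 9–10, 57/75) — with slope 0.9
fixed; the YAML records the calibrated value and the target.

What the generator deliberately does **not** emulate: longitudinal eye
growth between visits, age-dependent drift within a band, measurement
error correlated between eyes, ethnicity-specific biometry beyond the
two-preset contrast, and informative loss to follow-up. Passing tests
on generated cohorts therefore demonstrate the pipeline's statistical
correctness under a known model, not the indicator's performance on
real children — that is what the fixture cohorts, which are exact
reconstructions of the published counts, are for.

## Numerical and design notes

* Age routing: [6, 9) → 6–8 band, [9, 11) → 9–10 band; anything else
  errors, since no table exists outside those ages.
* The band-B (9–10) analyses use cut-off ≥ 4 of a 0–6 total; the
  Table-2 category bins are applied unchanged there (high risk
  unreachable, flagged above).
* Degenerate inputs fail loudly: single-class cohorts for ROC,
  zero-denominator metrics, all-zero fixture counts, unrealisable
  baseline truncation (a SER distribution almost entirely below
  −0.50 D) after a bounded number of rejection rounds.
* Problem sizes in the shipped tests were chosen to make the
  statistical checks sharp but quick: 1000 random cohorts of ≤ 50 for
  the oracle-equivalence suites, n = 5000 for preset incidence and
  slope-recovery checks (binomial/2-SE tolerances), 200 replicates ×
  400 resamples for bootstrap coverage, and n = 10000 for the
  zero-slope incidence sanity check.

## Worked example

```{r example}
fx <- premo_fixture(4, "uk_6_8")     # 57 children, reconstructed counts
scored <- premo_score(fx)
scored$myopic <- fx$outcome_myopic
scored$spearman_eligible <- TRUE

validation_report(scored, n_boot = 500, seed = 1) |>
  format_validation_report()
```

The PreMO row reproduces the published UK 6–8 performance: sensitivity
0.97 (32/33), specificity 0.96 (23/24), FPR 0.04 (1/24), optimal
cut-off 4, incidence 58%. The SER and AL rows use this same
score-fixture cohort, so they illustrate the report layout rather than
the published singular-predictor tables; those are reconstructed by
`premo_fixture(5, ...)` from their own counts.

## Known limitations

* The real validation datasets are not public; AUC and Spearman values
  on them depend on score distributions that the published tables do
  not determine, so the package reproduces every count-derived metric
  exactly but makes no claim to reproduce dataset-level AUCs.
* The indicator is defined only for ages 6–10 and for baselines
  measured under cycloplegia; applying it to non-cycloplegic
  refractions will misclassify accommodating children.
* Carried-forward outcome labels assume persistence of myopia; in
  populations where that assumption is weak the labels, and everything
  downstream, inherit the bias.
```
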