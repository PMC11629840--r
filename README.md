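# premor

Childhood myopia risk scoring with the PreMO indicator, and the
statistical pipeline to validate it on longitudinal cohorts.

## What problem this solves

Myopia that begins early in childhood progresses further and carries a
higher lifetime risk of sight-threatening disease, so optometrists want
to know *which* non-myopic children are on a myopic trajectory while
there is still time to intervene. The PreMO (Predicting Myopia Onset and
progression) risk indicator answers this with measurements already taken
in a routine paediatric eye exam: cycloplegic spherical equivalent
refraction (SER, dioptres), axial length (AL, mm) and parental myopia.
Points are assigned per factor in two age bands and summed:

| Band | Parental (0/1/2 myopic) | SER | AL | Total |
|---|---|---|---|---|
| 6–8 y | 0 / 2 / 3 | >+1.00 D → 0; +0.75–+1.00 → 2; <+0.75 → 3 | <22.94 mm → 0; 22.94– → 1; 23.12– → 2; ≥23.19 → 3 | 0–9 |
| 9–10 y | 0 / 1 / 2 | >+0.875 D → 0; +0.375–+0.875 → 1; <+0.375 → 2 | <23.33 mm → 0; 23.33– → 1; ≥23.62 → 2 | 0–6 |

Totals bin into risk categories (0 little/no risk, 1–3 low, 4–6
moderate, 7–9 high). Myopia is SER ≤ −0.50 D throughout; outcomes are
judged at age 15 or older. A total of **≥ 4** is the Youden-optimal
threshold for predicting who becomes myopic.

The package is aimed at researchers validating or extending the
indicator. Beyond the score itself it provides:

- **cohort I/O** — a child-level CSV schema with per-row validation,
  least-hyperopic-eye selection, and outcome labelling rules (including
  carrying documented pre-15 onset forward);
- **validation statistics** — ROC sweep with trapezoidal AUC,
  Youden-J optimal cut-off (ties broken toward sensitivity),
  sensitivity/specificity/FPR with count fractions, stratified
  percentile-bootstrap AUC intervals, Spearman correlation between
  score and outcome refraction, incidence, and a one-row-per-predictor
  report comparing the score against singular predictors
  (SER < +0.75 D, AL ≥ 23.07 mm);
- **synthetic cohorts** — exact fixture cohorts rebuilt from published
  contingency counts, plus a seeded generative model (truncated
  bivariate-normal biometry, logistic score-linked onset) with
  calibrated UK-like and Hong-Kong-like presets.

All user-facing functions take a data frame first and return tibbles,
so they chain with the pipe; fitted ROC objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Score one child, then reproduce a published validation row from its
printed counts:

```r
library(premor)

child <- tibble::tibble(
  child_id = "demo", age_years = 7.2,
  ser_right = 1.25, ser_left = 0.75,
  al_right = 22.90, al_left = 23.15,
  n_myopic_parents = 2
)
premo_score(child)
#>   child_id band    eye_used ser_used al_used parental_points ser_points al_points total category
#> 1 demo     age_6_8 left         0.75    23.2               3          2         2     7 high
```

The left eye is selected (least hyperopic), its AL travels with it, and
2 parents + SER in the 2-point band + AL in the 2-point band give a
total of 7: high risk, likely myopic by age 10.

```r
fx <- premo_fixture(4, "uk_6_8")          # 57 children from published counts
scored <- premo_score(fx)
scored$myopic <- fx$outcome_myopic
scored$spearman_eligible <- TRUE

validation_report(scored, list(predictor_spec("premo_score", 4)),
                  n_boot = 500, seed = 1) |>
  format_validation_report()
#>   predictor        auc_ci              sensitivity      specificity      fpr             optimal_cutoff spearman_rho incidence_percent
#> 1 premo_score >= 4 0.970 (0.898-1.000) 0.97 (n = 32/33) 0.96 (n = 23/24) 0.04 (n = 1/24)              4 -0.98                       58
```

Sensitivity 0.97 (32/33), specificity 0.96 (23/24), FPR 0.04, optimal
cut-off 4 and 58% incidence are exactly the published UK 6–8 row; the
AUC and Spearman values are properties of the reconstructed score
distribution, which the printed counts only partially determine.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/premo-cli.R fixture --table 4 --row uk_6_8 --out fx.csv
Rscript inst/scripts/premo-cli.R validate --cohort fx.csv --out report --seed 5
Rscript inst/scripts/premo-cli.R simulate --preset hk_6_8 --n 1000 --seed 7 --out sim.csv
```

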