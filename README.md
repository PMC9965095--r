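# frailscreen

Gender-stratified construction of the modified Fried physical-frailty
phenotype and evaluation of its components as screening markers.

## What it does, and for whom

Epidemiologists working with ageing-survey data often need to (a) build
the five-deficit frailty phenotype — exhaustion (E), weak grip strength
(G), slow walking time (W), unintentional weight loss (L), low physical
activity (P) — from raw measures, and (b) ask which single deficit, or
pair of deficits, best screens for the composite phenotype when measuring
all five is impractical. `frailscreen` implements both stages as a tested,
seeded pipeline:

* **Scoring** — dichotomisation of each deficit per the modified Fried
  rules (grip and walk cut at stratified low/slow-tail quantiles within
  sex × BMI and sex × height-median strata; questionnaire items by
  category), complete-case dropping, the 0–5 score
  `S = E + G + W + L + P`, and `frail = (S >= 3)`.
* **Screening accuracy** — for every component and every pair (parallel
  OR, or serial AND), the 2×2 table against the frail label and the five
  standard statistics

  `se = TP/(TP+FN)`, `sp = TN/(TN+FP)`, `PPV = TP/(TP+FP)`,
  `NPV = TN/(TN+FN)`, `prev = (TP+FN)/n`,

  each with a 95 % Wilson score interval with continuity correction
  (Newcombe), plus the Bayes consistency identities
  `PPV = se·prev / (se·prev + (1−sp)(1−prev))` and its NPV analogue.
* **Descriptives** — survey-weighted percentage distributions by sex and
  age group and Pearson chi-square tests of association.
* **Synthetic cohorts** — a latent-liability generator (one person-level
  liability driving all five deficits, with per-component loadings)
  emulating a ~31,000-person national ageing cohort of adults 60+, so the
  full analysis is reproducible without restricted microdata.

## Worked example

```r
library(frailscreen)

cfg    <- cohort_config(n_male = 2000, n_female = 2000, seed = 42)
cohort <- generate_cohort(cfg)
scores <- score_and_classify(cohort, target_scoring_config(cfg))
scores
#> frailty_scores: 4000 scored (0 of 4000 input rows dropped), 1323 frail (33.1%)

t3  <- evaluate_all_markers(scores)
sub <- t3[t3$sex == "male" & t3$components %in% c("G", "P", "G+P"), ]
format_accuracy_table(sub)
#>  sex                              marker        rule           sensitivity
#> male                       Grip strength      single   95.39 (93.28,96.88)
#> male                   Physical activity      single   92.32 (89.78,94.29)
#> male Grip strength and physical activity parallel_or 100.00 (99.19,100.00)
#>         specificity                 ppv                   npv          prevalence    n
#> 27.30 (25.01,29.72) 35.22 (32.88,37.64)   93.46 (90.52,95.57) 29.30 (27.32,31.36) 2000
#> 47.45 (44.83,50.10) 42.13 (39.42,44.89)   93.72 (91.62,95.33) 29.30 (27.32,31.36) 2000
#>  10.89 (9.34,12.66) 31.74 (29.63,33.93) 100.00 (96.97,100.00) 29.30 (27.32,31.36) 2000

round(rank_components(scores$flags[scores$flags$sex == "male", ]), 3)
#>     G     P     E     W     L
#> 0.793 0.642 0.380 0.155 0.059
```

Reading the output: among synthetic males, weak grip is by far the most
prevalent deficit (79.3 %) and, used alone, already catches 95.4 % of
frail participants; combining grip with physical activity in parallel
(positive if *either* deficit is present) pushes sensitivity to ~100 % at
the cost of specificity — the classic parallel-screening trade-off. Every
generated accuracy table satisfies the Bayes identities to machine
precision:

```r
validate_against_bayes(t3)$max_ppv_discrepancy
#> 3.33e-16
```

`run_pipeline(run_config(...))` executes all stages and writes the cohort,
cutoff, flag and table CSVs, a sensitivity/specificity figure, and a JSON
manifest with per-stage row counts; the same seed reproduces byte-identical
outputs. A thin command-line wrapper with `simulate` / `score` /
`evaluate` / `describe` / `run` / `selfcheck` subcommands lives at
`inst/cli/frailscreen.R`.

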