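---
title: "Frailty phenotype scoring and screening accuracy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frailty phenotype scoring and screening accuracy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailscreen)
```

## The problem

Physical frailty in community-dwelling older adults is commonly
operationalised with the modified Fried phenotype: five binary deficits —
exhaustion (E), weak grip strength (G), slow walking time (W),
unintentional weight loss (L) and low physical activity (P) — summed into
a 0–5 score, with "frail" defined as three or more deficits. Screening all
five components is impractical in many primary-care settings, so a natural
question is how well each component, or a pair of components, performs as
a cheap proxy screen for the full phenotype. `frailscreen` implements that
analysis end to end, gender-stratified, for cohorts shaped like a large
national ageing survey of adults aged 60+, and ships a synthetic cohort
generator so the whole pipeline is testable and reproducible without
restricted microdata.

## The phenotype construction

The dichotomisation rules are:

* **Exhaustion** — a CES-D tiredness/low-energy frequency item; answering
  "often (3–4 days)" or "most (5–7 days)" in the last week flags the
  deficit.
* **Weak grip strength** — the mean of two dynamometer trials of the
  dominant hand (kg). A participant is flagged when the mean falls in the
  low tail of their sex × BMI stratum; by default BMI quartiles within
  sex (eight strata), the original phenotype operationalisation, with a
  sex × BMI-median variant available.
* **Slow walking time** — the mean of two timed 4-m walks (s), flagged in
  the *slow* tail of the sex × height-median stratum.
* **Weight loss** — self-reported weight loss in the last 12 months due to
  insufficient food.
* **Low physical activity** — sports/vigorous activity 1–3 times a month
  or less.

A missing component (e.g. both grip trials absent) drops the row before
scoring (complete-case analysis); the drop count is reported. When only
one trial of a measure is present it stands in for the mean, which
maximises complete cases. Stratum cutoffs are derived *after* the
complete-case drop (on the rows actually scored); externally derived
cutoff tables can be supplied instead. The score `S` is the sum of the
five flags and `frail = (S >= frail_threshold)` with the conventional
threshold of 3.

### Quantiles, ties and direction

Cutoffs use the lower-value (type-1) quantile: the smallest observed value
whose cumulative fraction reaches `p`. This is deterministic, invariant to
row order, and exactly checkable against a sort-and-index oracle, which the
test suite does exhaustively on small strata. Values exactly at a threshold
are flagged by default (`flag_at_or_below`), so every stratum's flagged
fraction is at least `p` and within one observation of it when values are
distinct; with heavy ties a stratum can degenerate to 100 % flagged, which
is surfaced rather than hidden. For walk time the phrase "bottom quintile
of the time values" is ambiguous — literally it is the *fastest* 20 %, but
the construct being measured is slowness. The default flags the slowest
20 % (`walk_direction = "slowest_flagged"`); the literal reading remains
available and is labelled non-standard. Quantiles are unweighted by
default (survey weights are reserved for percentage distributions); a
survey-weighted quantile variant is provided.

### The tail proportion is configurable for a reason

A strict in-sample bottom-quintile rule flags ~20 % of each stratum by
construction. Published prevalence tables for this phenotype, however,
report weak-grip prevalences near 79 % (males), which is only possible if
the dichotomisation cutoffs came from outside the analysis sample (for
example, from the full 45+ survey population rather than the 60+ analysis
subset). `quintile_proportion` therefore accepts either a single
proportion (default 0.20, the stated rule) or per-measure, per-sex
proportions. `target_scoring_config()` builds the latter from a
generator's marginal prevalence targets, emulating an analysis whose
cutoffs were fixed externally — this is the configuration used to
reproduce the published tables' shape.

## Screening accuracy

Each component, and each of the ten unordered component pairs, is screened
against the composite frail label per sex: a 2×2 table (TP, FP, FN, TN)
and the standard definitions sensitivity TP/(TP+FN), specificity
TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN), prevalence (TP+FN)/n. Pairs
combine in parallel (OR) by default: a pair is positive when either
deficit is present. This choice follows from the algebra of combined
tests — parallel combination can only raise sensitivity above, and lower
specificity below, both members, which is exactly the signature the
published combined-marker rows show; serial (AND) combination is provided
for completeness and satisfies the dual specificity bound. Both
dominance relations are property-tested across seeded cohorts.

Zero-denominator metrics (e.g. sensitivity in a stratum with no frail
participants) are reported as undefined with the metric named, never
silently coerced to 0 or 1.

### Confidence intervals

Every metric carries a 95 % Wilson score interval with continuity
correction (Newcombe's closed form), computed on the metric's own natural
denominator. The boundary rules set the lower limit to 0 at an observed
proportion of 0 and the upper limit to 1 at 1. The implementation is
validated exhaustively against an independent continuity-corrected
score-test inversion (root search on the defining inequality) for every
(successes, n) with n ≤ 50, to 1e-10. The published tables' own interval
widths depend on per-metric denominators the source does not state, so
printed intervals are not used as test oracles; the closed form is
validated by inversion instead.

### The Bayes identities as an internal-consistency check

PPV and NPV are determined by sensitivity, specificity and prevalence:

$$\mathrm{PPV} = \frac{se \cdot \pi}{se \cdot \pi + (1-sp)(1-\pi)},
\qquad
\mathrm{NPV} = \frac{sp(1-\pi)}{sp(1-\pi) + (1-se)\pi}.$$

On tables built from exact counts the identities hold to machine
precision, and `validate_against_bayes()` checks every generated marker
table against them. Applied to a published table re-entered at 2-decimal
precision, the identities also quantify internal consistency: on
well-conditioned rows the printed inputs determine the printed PPV/NPV to
the same 2 decimals (rounding propagation stays below 5e-4 on the
proportion scale), and the test suite verifies ten such cells. Rows with
extreme specificity/prevalence combinations are more sensitive to input
rounding and can drift by up to ~0.07 percentage points, which is why the
check is restricted to well-conditioned cells.

## The synthetic cohort generator

The generator emulates the analysis sample's *statistical structure*, not
the survey's sampling design. Each person carries a latent liability
$Z \sim N(0,1) + \delta_{\text{age}}$ with $\delta = (0, 0.3, 0.6)$ for
ages 60–69 / 70–79 / 80+. Each component has an underlying scale
$U_j = \rho_j Z + \sqrt{1-\rho_j^2}\,\varepsilon_j$; grip strength
decreases in $U_G$ (normal, sex-specific mean, two noisy trials), walk
time is log-normal increasing in $U_W$, and the three questionnaire items
are assigned by within-sex rank of their $U_j$ so that the flagged-category
marginals hit the configured targets exactly. Survey weights are
log-normal with mean 1 and configurable dispersion — they only need
positivity and heterogeneity to exercise weighted estimators. Covariate
categories are drawn per sex from the published background-table
marginals, independently of age and of the liability.

Default sizes are 14,885 males and 16,093 females (the published analysis
sample); default component targets are the published per-sex weighted
prevalence totals (males: E 37.94 %, G 79.07 %, W 15.40 %, L 5.85 %,
P 64.21 %; females: E 39.54 %, G 67.09 %, W 26.31 %, L 5.53 %, P 81.63 %).

### Calibrating the dependence, and a structural limit

The source material specifies the five marginals and the composite
prevalence but no joint model, so the inter-component dependence is a free
parameter. The loadings were calibrated once, by moment-matching the male
composite prevalence, to $\rho = (E\,0.12, G\,0.15, W\,0.18, L\,0.08,
P\,0.15)$, giving a male composite of ≈ 29.4 % against the published
27.85 %. Two facts constrain this choice and are worth recording:

* With the published *female* marginals, the composite prevalence under
  component independence is already 36.8 % — above the published female
  composite of 33.16 %. Since a single-factor model with non-negative
  loadings can only increase the tail probability $P(S \ge 3)$ beyond the
  independence value, *no* such generator can match the published female
  composite together with its own published marginals. (The published
  numbers are survey-weighted and subject to missing-data structure the
  generator does not model, which is presumably where the gap originates.)
  The generator's female composite lands near 37 %.
* Stronger loadings (or larger age shifts) steepen the age gradients
  toward the published age-specific prevalences but push both composites
  further up. The defaults keep gradients strictly monotone — mean grip
  falls and mean walk time rises with age group, which is asserted as an
  invariant — but shallower than the published age-specific values.

Consequently, passing tests demonstrate marginal recovery, rank recovery
(grip most prevalent in males, physical activity in females), monotone age
structure, and the full accuracy geometry (headline sensitivities above
90 %, OR-pair sensitivity above 99.8 %); they do not certify the
generator as a re-creation of the restricted microdata's joint
distribution, its cluster sampling, or its weight construction.

## Descriptive tables and tests

Percentage distributions use the survey weight:
$\mathrm{pct}(c) = 100 \sum_{i: x_i = c} w_i / \sum_i w_i$, per sex and
age-group column (columns sum to 100). Association between a covariate's
categories and age group within sex is tested with the Pearson chi-square
on unweighted counts — the "chi-square test" of the field's bivariate
tables; design-corrected (Rao–Scott) variants are out of scope. The
statistic is cross-checked against the textbook formula and against the
squared two-proportion z-statistic on 2×2 tables. p-values display as
three decimals with a `<0.001` rule.

## Problem sizes used in the checks

The shipped checks run the generator at the full default sizes (≈ 31,000
rows) for marginal/rank recovery, 100 seeded cohorts of 2,000 for the
dominance invariants, 1,000 random strata for quintile coverage, all
(successes, n ≤ 50) pairs for the interval oracle, and all 2×2
configurations with n ≤ 12 for the metrics oracle. These sizes give
Monte-Carlo error comfortably inside the asserted bands while keeping a
full run in the order of two minutes on one core.

## Known limitations

* The generator's covariates are independent of age and liability, so
  covariate-by-age associations are null by construction; the descriptive
  module is validated on structure (weighting, margins, test mechanics),
  not on reproducing published covariate gradients.
* Weighted 2×2 mode feeds weight sums through the same interval formulas
  as counts; no design-based effective-sample-size correction is applied.
* ROC/AUC analysis is out of scope (the components are already binary),
  as are triple-or-more marker combinations and imputation of missing
  components.
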