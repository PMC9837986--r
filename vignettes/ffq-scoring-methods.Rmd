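---
title: "FFQ nutrient scoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FFQ nutrient scoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffqscore)
```

## The scoring model

A food-frequency questionnaire records, for each listed food item, how
often it was eaten over a recall window and how much per occasion. The
engine converts those answers to grams per day,

$$g_{ij} = \text{portion}_{ij} \times \frac{\text{occurrences}_{ij}}{\text{period}_{ij}},$$

looks up the per-100 g nutrient vector for the item (after resolving the
"type" follow-up question that distinguishes e.g. fried from cooked
preparations or sweetened from unsweetened drinks), scales it by
$g_{ij}/100$, and sums over items. Energy is carried in kcal; protein,
fat, carbohydrates, fiber and sugar cross an mg-to-g boundary exactly once
at the intake table; all remaining nutrients (fiber subclasses, tyrosine,
tryptophan, the fatty-acid classes, omega-3/6) stay in mg/d. The fiber
subclasses default to mg/d because published intake tables are not
consistent about their unit; a gram-level view is one `mutate()` away in a
tibble-based workflow, so we keep the unambiguous unit in the container.

Two assumptions are load-bearing. First, *category values are data*: the
schema config carries every frequency category (occurrences over a period
in days) and portion category (grams per occasion), so instruments with
different recall windows — 24 h up to 4 weeks — flow through identical
code once frequencies are normalised per day. Second, *variant selection
is single-choice*: the type question picks exactly one reference entry per
item, which matches how the instrument asks the question.

### Missing answers

An unanswered or unresolvable item is excluded from the totals, counted in
`items_missing`, and logged — it is not imputed as zero, because
self-report instruments do not distinguish "never eats this" from "did not
answer". `missing_as = "zero"` reproduces the more permissive convention
where an omitted item counts as non-consumption. Unknown (empty) nutrient
cells in the reference table are distinct from zero and propagate as `NA`
totals whenever a consumed item touches them.

## Outlier filtering and energy adjustment

Energy outliers are flagged by the interquartile-range rule: strictly
above $Q_3 + 1.5\cdot IQR$ or strictly below $Q_1 - 1.5\cdot IQR$.
Quartiles use R's default linear-interpolation convention
(`quantile(type = 7)`); the convention is a parameter because published
analyses rarely state one, and the package's own tests recompute the
bounds under the configured convention by brute force. Filtering operates
per recall-window stratum by default: a 24-hour report and a 7-day report
describe differently scaled quantities, and pooling them would let one
window's tail define the other's fences. `per_window = FALSE` pools.

Energy adjustment follows the residual method: ordinary least squares of
the nutrient on total energy over the analysis stratum, with the residual
as the energy-independent measure. Residuals sum to zero and are
uncorrelated with energy by construction — both are asserted to 1e-9 in
the tests. `mode = "residual_plus_mean"` adds back the prediction at the
cohort-mean energy, which preserves the cohort mean of the nutrient
exactly and keeps interpretable units. The fit uses all rows the caller
passes; fitting within subgroups (e.g. per sex) is done by grouping the
table first, a deliberate choice to keep stratification explicit rather
than hidden behind a flag.

## Reliability statistics

Test-retest agreement uses Pearson's $\rho$ and ICC(2,1): two-way random
effects, single measures, absolute agreement,

$$ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

where $MS_R$, $MS_C$, $MS_E$ are the between-subject, between-measurement
and error mean squares of the two-way ANOVA decomposition. Absolute
agreement (rather than consistency) is the right choice for repeated
administrations of the same instrument because a systematic shift between
visits is a real disagreement. The 95% CI is the standard F-based interval
for this estimator. Interpretation follows the Koo–Li bands (poor < 0.5 ≤
moderate < 0.75 ≤ good < 0.9 ≤ excellent); boundary values go to the
higher class, a convention we document because the bands are stated as
open/closed inconsistently in secondary literature.

The implementation is in-package (no ICC dependency is available in the
target environment); the test suite cross-checks it against an independent
`stats::aov` sums-of-squares oracle to 1e-10 on randomised matrices.
Complete cases only: a subject missing either administration contributes
to neither $n$ nor the mean squares, and the $n$ actually used is
reported. The same pairwise-deletion policy runs through every statistic
in the package, since repeated FFQ studies routinely have unequal ns per
visit.

Group comparisons default to Welch's t-test (`var_equal = TRUE` gives the
classic Student test) because equal variances between, say, high- and
low-consumption groups is exactly the kind of assumption that fails in
intake data; the chi-squared test of independence is the uncorrected
Pearson statistic by default so that it matches the closed-form
$(O-E)^2/E$ sum, with Yates correction behind a flag.

## The synthetic generator

The generator exists so the full pipeline — schema validation, scoring,
filtering, adjustment, reliability — can be exercised with known ground
truth and without licensed food-composition data. It emulates:

- **Latent intake**: per-subject daily energy is log-normal (non-negative
  and right-skewed, as intake self-reports are), with defaults of
  2000 kcal/d mean, 450 kcal/d SD, +300 kcal/d for males, and a
  ±415 kcal/d offset for the high/low fat-and-sugar groups — magnitudes
  chosen to match the cohort descriptives this class of study reports.
- **Habitual diet**: each subject carries a stable item-weight profile
  (food-group energy shares perturbed per item), so between-subject
  variance exceeds within-subject variance. Vegetarian profiles zero the
  meat/fish weights, redistribute them to plant groups and up-weight
  fiber-rich groups by `veg_fiber_multiplier` (default 1.3).
- **Test–retest structure**: timepoint latents share a common factor so
  any two timepoints correlate at `retest_rho` (default 0.6, a typical
  moderate FFQ reliability). Short windows get extra log-scale noise
  (`window_noise_sd`, default 0.8 for 24 h, 0 otherwise) and a mean offset
  (default +300 kcal/d for 24 h): single days genuinely vary more than
  weekly habits, and short-window reports tend to run higher.
- **Quantisation**: latent grams/day are mapped to the nearest grams/day
  value reachable by the item's frequency × portion grid (ties broken
  toward the smaller category, deterministically). The induced bias is
  measured and reported by the generator (`quantization_bias_pct`), never
  hidden; `quantize = FALSE` emits free-gram answers for exact recovery.
- **Macronutrient composition**: the demo reference table draws per-item
  compositions from food-group priors with energy tied to macronutrients
  by Atwater factors, and the food-group energy shares were calibrated
  once so a default cohort lands near mass shares of 58.5% carbohydrate /
  16.5% fat / 19% protein / 6% fiber with sugar at ~45% of carbohydrate.
  Achieved shares are reported per run, and a warning fires when a
  requested profile is not reachable under the schema's categories.

What it does **not** emulate: correlated day-to-day menus (no weekday /
weekend structure), social-desirability or differential misreporting
(under-reporting in real cohorts is substantial and selective), item-level
seasonal effects, and real food-composition values — the demo table is
plausible, Atwater-consistent noise, not a measured database. Passing
tests therefore demonstrate that the *engine* is correct and that the
statistics behave as designed on data with the right broad structure; they
say nothing about the accuracy of any particular nutrient database or
about real respondents.

All randomness flows from a single integer seed per generating call;
sub-draws are consumed in a fixed documented order, so identical seeds
give identical cohorts.

## The shipped schema

`degs1_schema()` loads a 53-item instrument with 16 type questions, the
structure of the DEGS1 questionnaire. The original category tables
(portion grams, frequency occurrences) are distributed with the instrument
itself and are not redistributable here; the shipped
YAML therefore carries synthetic representative values and says so in its
filename and header. Analyses of real DEGS1 exports should replace the
category values with the instrument's own tables — the engine treats them
as data, so no code changes.

## Numerical choices and degenerate inputs

- Quartiles: `type = 7` linear interpolation; outlier bounds use strict
  inequalities, so an all-equal energy column (IQR 0) flags nothing.
- Fewer than 4 energy values per stratum: error (quartiles unstable), as
  does adjustment on fewer than 3 complete rows or constant energy.
- ICC on fewer than 5 subjects warns; zero total variance errors. When the
  estimate is exactly 1 the CI degenerates to the point estimate.
- A paired t-test on identical vectors returns statistic 0, p 1 by
  convention; any other zero-variance configuration errors.
- Answer codes are lower-cased and trimmed on read; free-gram amounts are
  accepted wherever a portion code is expected.
- Scoring is permutation-invariant and additive over item-disjoint partial
  records; both are asserted as properties in the tests.

## Problem sizes

The test suite and the acceptance script run cohorts of 200–500 subjects
with two timepoints and up to two recall windows, and 100 seeded
replicates for the window-ordering check — sizes chosen to put Monte-Carlo
error well below the effects being checked (e.g. the SE of a correlation
at n ≈ 500 is ~0.03 against a ±0.08 recovery band) while keeping a full
run in the low minutes on a single CPU.

## Known limitations

- The reliability table assumes exactly two measurements per pairing
  (k = 2); the ICC itself accepts any k.
- Weighted variant mixtures (e.g. "half fried, half cooked") are not
  implemented; the type question is single-choice as in the instrument.
- Linear mixed models predicting anthropometry from adjusted intakes are
  out of scope; `adjust_nutrients()` output is the analysis-ready table
  such models would consume.
- The under-reporting factor of real cohorts is not modelled; simulated
  intakes are unbiased apart from reported quantisation bias.
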