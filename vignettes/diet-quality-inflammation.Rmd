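---
title: "Methods: diet-quality scoring and inflammation association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-quality scoring and inflammation association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(dietquality.quiet = TRUE)
library(dietquality)
```

This vignette is the package's account of its methods: the intake model, the
six adherence indices and every tunable constant behind them, the regression
and power machinery, the synthetic-cohort generator, and the numerical and
design choices that were genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. From FFQ responses to daily intake

The intake model is deliberately simple and linear. A response in frequency
category $c \in \{1,\dots,9\}$ for item $i$ contributes

$$\text{grams/day}_i = f(c)\; \cdot\; \pi_i \cdot s_i,$$

where $f$ maps the category to mean occasions/day, $\pi_i$ is a per-item
portion fraction, and $s_i$ the serving size in grams. Group serves/day are
$\sum_i \text{grams}_i / s_i$ over items carrying the group tag (multi-tag
items count toward every tag they carry); nutrients/day are
$\sum_i \text{grams}_i \times d_{i,k}/100$ for per-100 g density $d_{i,k}$.
Consequences that the tests exploit: intake is linear in the frequency
multipliers and additive over disjoint response sets.

Tunable parameters:

* **Frequency scale** (`default_frequency_scale()`): occasions/day for the
  nine categories, default `0, 2/30.44, 1/7, 3/7, 5.5/7, 1, 2.5, 4.5, 6`.
  The instrument itself does not print multipliers; these are the
  conventional EPIC-style values (a mean month of 30.44 days, weekly
  categories at their midpoint rate). Any non-negative, non-decreasing
  9-vector is accepted.
* **Portion fraction** $\pi_i$: a per-item multiplier in the
  composition-table schema, default 1.0. The concept of scaling portions by
  reporting frequency is not given a formula by the source instruments, so
  it is exposed as data rather than hard-coded.
* **Energy conversions** (`energy_conversions()`): 17 kJ/g carbohydrate and
  protein, 37 kJ/g fat, 29 kJ/g alcohol (Atwater-style).
* **Missing responses** are zero intake. This is the conservative reading of
  an unanswered FFQ line; it biases scores toward non-adherence rather than
  inventing consumption.
* **Open section**: qualifiers re-point a generic base item (e.g. `milk`) to
  a variant (`milk_skim`), swapping densities and tags. Unmatched qualifier
  names or values are logged and ignored rather than failing the run,
  because free-text sections are noisy by nature.

## 2. Lifestyle covariates

* **GPAQ**: MET-minutes/week $= \sum \text{days} \times \text{minutes}
  \times w$, with $w = 8$ for vigorous work/recreation and $w = 4$ for
  moderate work, travel and moderate recreation; classes are <600 (low),
  600–1500 (moderate), ≥1500 (high) MET-min/week, tested exactly at the
  boundaries.
* **Blood pressure**: the first of three seated readings is discarded and
  the second and third averaged; the first reading provably has no influence.
* **Energy requirement**: Schofield age/sex-band BMR equations (kJ/day)
  multiplied by an activity factor of 1.4/1.6/1.8 for the low/moderate/high
  class. The factors span the conventional sedentary-to-active range and are
  arguments, not constants. The cited basis for the original computation is
  a generic "BMR × activity factor" prescription, so the equation set is
  replaceable.
* **DASH calorie level**: the nearest of 1600/2000/2600/3100 kcal compared
  on the kJ scale. An exact midpoint (within 1e-9 kJ) resolves to the
  *lower* level — conservative targets — and requirements beyond the extremes
  clamp. The mapping is monotone and idempotent by construction.

## 3. The six indices

All component targets, limits and thresholds live in
`default_score_config()` and ship as `inst/extdata/score_config.yaml`. The
source publications define their cut-points in supplementary scoring tables
that are not reproduced here; defaults are transcribed from the public
source instruments (the NHLBI DASH eating plan servings, the Loma Linda
vegetarian food-guide pyramid, HEIFA-2013, the published 14-item MEDAS and
the PREDIMED-Plus 17-item screener). Keeping them in a versioned config
makes every unverifiable constant auditable and overridable without touching
the algorithms.

**DASH (0–80).** Six 10-point components (fruit incl. juice; vegetables
incl. potato; meat/poultry/fish/eggs reverse; nuts/seeds/legumes; fats and
oils reverse; sweets reverse) and four 5-point components (total dairy;
low-fat dairy share; whole grains; high-fibre grains), with serves targets
per assigned calorie level. Forward scoring is proportional,
$p = \min(x/t, 1)\,m$; reverse scoring awards $m$ at or below the target and
decays as $m\,t/x$ above it — a bounded, continuous choice among the many
curves compatible with "reverse scoring". A reverse target of 0 (the sweets
target at the 1600 kcal level) awards full points only at zero intake, the
continuous limit of $t/x$. The low-fat share component scores
$5\min(\text{share}/0.75, 1)$ with share 0 when no dairy is consumed, so an
empty diet scores exactly the sum of the reverse maxima (30).

**Dairy-adjusted DASH (0–80).** The low-fat-share component's 5 points are
granted unconditionally. The alternative — dropping the component for a 0–75
scale — was rejected to keep composites comparable across the two variants;
the dominance property (adjusted ≥ unadjusted, equality iff the low-fat
criterion was already met) is tested. Whether the original variant kept the
0–80 scale is not documented; this is our choice, stated openly.

**Vegetarian Lifestyle Index (0–14).** Eleven diet components scored
0/0.5/1 on serves standardised to 2000 kcal (8368 kJ) via
$x^\ast = x \cdot 8368/\text{EER}$, plus three lifestyle components:
exercise (1 at the high activity class, 0.5 moderate), water (1 at a diary
water fraction ≥0.5, 0.5 at ≥0.25) and sunlight, which defaults to the full
point — appropriate for a subtropical setting where minutes of daily sun
suffice for vitamin D synthesis — and is an argument otherwise. The
standardisation makes the score invariant to proportional changes of intake
and requirement, which is tested. The index is occasionally presented on a
0–15 scale elsewhere; this implementation follows the 14-component
formulation whose points sum to 14.

**HEIFA (0–100).** Nine 0–10 components and two 0–5 components. Vegetables
and fruit split their 10 points equally between quantity (proportional to
target serves) and variety (proportional to a distinct-items-consumed count,
computed from the FFQ at a ≥5 g/day threshold — a proxy, since a food
*frequency* instrument has no true within-group variety question). Grains
split between quantity and wholegrain share (full sub-score at ≥50%).
Saturated fat is scored on percent of energy: full below 10%E, zero at 15%E
or more, linear between; added sugar (15/20%E) and sodium (2000/3600 mg)
use the same linear-band form. Between-threshold interpolation is linear
because nothing sharper is defensible. Discretionary foods band from 2.5 to
6 serves. Water scores $5\min(w/0.5, 1)$ on the diary water fraction;
alcohol is 5 at ≤2 serves/day, else 0.

**MEDAS (0–14) and erMedDiet (0–17).** One binary point per criterion
(quantity thresholds or yes/no habits), summed. The 17-item variant drops
the olive-oil quantity question and adds whole-grain, white-bread,
refined-grain and no-added-sugar-in-drinks items. The 13 criteria shared
between the two screeners use identical default cut-offs, so identical
answers give identical points on the shared set (tested); energy-restricted
tightenings, which the source supplements do not enumerate, can be applied
in the config. Missing answers: strict mode (default) errors naming the
criterion and participant; lenient mode scores 0 with a logged warning.
When screener answers are derived from the FFQ rather than asked directly,
weekly criteria are evaluated as day rate × 7, and the three questions an
FFQ cannot answer (main cooking fat, sofrito, sugar in tea/coffee) come
from the open section / covariate flags.

## 4. Inference

* **Transformation.** hsCRP and PAF are right-skewed and natural-log
  transformed; Lp-PLA2 is analysed raw. Natural (not base-10) logs are
  forced by the back-transformation convention: a fitted coefficient β on a
  log outcome yields `exp(β)` as a multiplicative effect and
  `100(1 − exp(β))` as percent reduction. Automated normality routing uses
  Shapiro–Wilk at α = 0.05 as the reproducible stand-in for visual Q–Q
  inspection.
* **Models.** OLS with the outcome and continuous predictors (score, age,
  waist) z-scored, binary covariates (gender, 2022 vs 2021, high vs low
  risk) as 0/1 indicators, and activity entered as the 0/1/2 ordinal (the
  dummy coding is a one-line change; the ordinal was chosen as the more
  parsimonious default). Model 1: age, gender, year; model 2 adds waist,
  activity and risk, with activity omitted for the Vegetarian Lifestyle
  Index because exercise is a component of that score. Complete-case per
  model; rank deficiency is a hard error naming the collinear columns.
  Exponentiating a *standardised* coefficient and reading it as a per-point
  effect conflates per-SD and per-unit scales; the package reproduces that
  convention at presentation while exposing `beta_std`, `se` and the CI so
  users can rescale. VIF is the diagonal of the inverse correlation matrix
  of the design (tolerance its reciprocal), cross-checked against
  `car::vif()` in the tests.
* **Quartiles.** Rank-percentile bins at the 25/50/75 quantiles with
  boundary values in the lower bin; descriptive only.
* **Power.** Fisher-z: $\Phi(-z_{1-\alpha/2} + \sqrt{n-3}\,\mathrm{atanh}\rho)
  + \Phi(-z_{1-\alpha/2} - \sqrt{n-3}\,\mathrm{atanh}\rho)$; simulation:
  bivariate-normal draws with `cor.test()` rejections. At n = 100,
  ρ = 0.3, α = 0.05 both routes give ≈0.86, consistent with an 80%-power
  design justification.

## 5. The synthetic-cohort generator

`generate_cohort()` emulates the *structure* of a 100-participant
cross-sectional study: 69% female, 68% high CVD risk, a 46/54 split across
two collection years, FFQ + open section, GPAQ, triplicate blood pressure,
a 3-day beverage diary, and three biomarkers — log-normal hsCRP (meanlog
log 0.96, sdlog 1.1) and PAF (meanlog log 7.96, sdlog 1.0), Gaussian
Lp-PLA2 (14.9 ± 4.3 with a +3 male shift). Location/spread are loose
approximations chosen once to be realistic for a mixed-risk adult cohort;
they are not fitted to any dataset.

Two generator design choices matter for interpretation:

1. **FFQ link.** A latent diet-quality factor $z \sim N(0,1)$ shifts each
   item's frequency category through an ordered-threshold link (healthier
   items up, unfavourable items down, gain 1.6 categories/SD, response
   noise SD 1.2, rounded and clamped to 1..9). This guarantees a monotone
   score–factor relationship without per-item tuning and induces positive
   correlations among all six computed scores.
2. **Biomarker conditioning.** Biomarkers are drawn linearly in the
   *standardised computed DASH composite* (the realised diet-quality
   factor), not in the raw latent $z$: log-hsCRP
   $= \mu + \sigma(\beta s + \sqrt{1-\beta^2}\,\varepsilon)$ with default
   $\beta = -0.35$. Conditioning on the realised score makes the configured
   effect the exact estimand of the downstream standardised regression —
   otherwise the latent-to-score measurement link would attenuate every
   recovery check by an unknowable factor. The year-on-PAF shift is off by
   default and switchable to exercise the stratified analysis.

What the generator does **not** emulate: real food-composition data (the
fixture table is ~45 synthetic items, not a national database), seasonal or
energy-misreporting structure, within-person day-to-day variance,
between-score differential validity, and any COVID-era biology behind a
year effect. Passing tests therefore demonstrate the *pipeline's*
correctness and calibration, not nutritional claims about real diets.

Problem sizes used by the test suite, chosen as the package's own
trade-off between Monte-Carlo error and runtime: 200 cohorts of n = 100 for
effect recovery (mean fitted β within ±0.02 of −0.35), 1000 cohorts for the
type-I error check (rejection rate in [0.03, 0.07] at α = 0.05), 10,000
replicates for simulation power, and 20 cohorts for the distribution-shape
checks.

## 6. Degenerate inputs and numerical conventions

Zero total energy is a domain error for percent-of-energy and HEIFA; zero
beverage volume across all diary days is a domain error for the water
fraction; non-positive concentrations are a domain error for the log
transform, naming the participant. Constant columns yield a flagged NA
correlation, never a silent 0. Unknown composition-table items fail loudly
with the item id. Oracle-equivalence tests on small fixtures run at 1e-9
relative tolerance; exact-identity properties (VIF × tolerance,
permutation invariance) at 1e-12.

## 7. Known limitations

* Index cut-points are transcriptions of the source instruments, not of any
  study-specific supplementary scoring tables; results under other
  transcriptions are reachable via the YAML config but not validated here.
* The FFQ-derived screener answers and variety counts are proxies for
  questions the source screeners ask directly.
* The per-SD vs per-point tension in exponentiating standardised
  coefficients is reproduced, documented, and not resolved.
* CVD risk class is consumed as a label; the package does not re-derive it
  from lipids/blood pressure.

```{r example}
profile <- generate_full_adherence_profile("dash")
score_full_adherence(profile)

cohort <- generate_cohort(cohort_config(n = 100, seed = 1))
scored <- score_cohort(cohort$ffq, cohort$covariates, cohort$table,
                       cohort$open_section)
frame <- build_analysis_frame(scored$composites, cohort$covariates,
                              scored$activity)
fit_model(frame, "log_hscrp", "dash", model_id = 1)
```
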