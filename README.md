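# dietquality

Diet-quality index scoring and inflammation-association analysis for
cross-sectional nutritional epidemiology.

Cohort studies that relate habitual diet to inflammatory biomarkers
typically (1) quantify intake from a semi-quantitative food frequency
questionnaire (FFQ) via a food-composition table, (2) condense the diet into
adherence scores against named dietary patterns, and (3) regress
(log-transformed) biomarker concentrations on those scores with demographic
and clinical covariates. `dietquality` implements that chain as a tested,
reusable R pipeline, aimed at researchers who want to score their own cohort
or to study the statistical behaviour of the design on synthetic data.

## What it computes

**FFQ engine.** A 9-point frequency response (never/<1 per month ... 6+ per
day) for each food item is converted to occasions/day, multiplied by a
per-item portion fraction and serving size (g) to give grams/day, then
aggregated into food-group serves/day (grams ÷ serving size, summed over
items carrying the group tag) and nutrients/day (grams × per-100 g density).
Open-section qualifiers (milk type, cooking fat) substitute variant items.

**Six diet-quality indices**, all cut-points held in an auditable YAML
configuration:

| Index | Scale | Structure |
|---|---|---|
| DASH | 0–80 | six 10-point + four 5-point components, targets per assigned calorie level (1600/2000/2600/3100 kcal), proportional and reverse scoring |
| Dairy-adjusted DASH | 0–80 | DASH with the low-fat-dairy share requirement removed |
| Vegetarian Lifestyle Index | 0–14 | 11 diet + 3 lifestyle components scored 0/0.5/1, serves standardised to 2000 kcal |
| HEIFA | 0–100 | 9 components 0–10 (incl. variety and wholegrain-share subrules, saturated fat as % energy) + water and alcohol 0–5 |
| MEDAS | 0–14 | 14 binary adherence criteria |
| erMedDiet | 0–17 | 17 binary criteria (energy-restricted variant) |

**Lifestyle covariates.** GPAQ MET-minutes/week (weights 8 vigorous, 4
moderate/travel) and the <600 / 600–1500 / ≥1500 activity classes; BMI;
triplicate blood pressure averaging (first reading discarded); Schofield
BMR × activity factor for the estimated energy requirement and DASH
calorie-level assignment; diary water fraction.

**Inference.** Natural-log transformation of right-skewed biomarkers;
t-test / Mann–Whitney group comparisons; pairwise Pearson correlations with
Cohen magnitude labels; two OLS models with standardised coefficients
(model 1: age, gender, collection year; model 2: + waist circumference,
physical activity, CVD risk class, with activity omitted for the Vegetarian
Lifestyle Index, which already contains it); VIF/tolerance collinearity
diagnostics; exponentiated-coefficient back-transformation, where a
coefficient β from a natural-log outcome model gives `exp(β)` as the
multiplicative effect and `100 × (1 − exp(β))` as the percent reduction per
one-point score increase; score-quartile descriptive means; and Fisher-z or
simulation power for the Pearson correlation test.

**Synthetic cohorts.** `generate_cohort()` simulates the complete input file
set (FFQ, open section, GPAQ, blood pressure, 3-day beverage diary,
demographics, biomarkers) from a latent diet-quality factor, with a
configurable standardised effect of the diet score on log-hsCRP (default
−0.35) and on the other biomarkers (default 0), so the whole pipeline is
testable without participant data.

## Worked example

```r
library(dietquality)

cohort <- generate_cohort(cohort_config(n = 100, seed = 42))
scored <- score_cohort(cohort$ffq, cohort$covariates, cohort$table,
                       cohort$open_section)
head(scored$composites, 3)
#>   participant_id dash dash_dairy_adjusted vegetarian_lifestyle heifa medas ermeddiet
#> 1           P001 72.4                72.4                 10.0 100.0    11        15
#> 2           P002 47.1                50.7                  7.5  75.4     6         8
#> 3           P003 64.6                65.2                 10.0  92.0     9        11

frame <- build_analysis_frame(scored$composites, cohort$covariates,
                              scored$activity)
fit_model(frame, "log_hscrp", "dash", model_id = 1)
#> <model 1: log_hscrp ~ dash> n = 100, beta_std = -0.362 (p = 0.000258),
#>   exp(beta) = 0.697 (-30.3%)

power_pearson(n = 100, rho = 0.3, alpha = 0.05)
#> [1] 0.8618022
```

The fitted standardised coefficient (−0.362) recovers the configured −0.35
effect up to sampling error; `exp(β) = 0.697` says each one-point increase
in DASH adherence is associated with a ~30% lower hsCRP in this synthetic
cohort. `analyze_scores(frame, out_dir = ...)` writes the full table set:
score–score and score–marker correlations, both models per score × outcome,
year-stratified re-fits, and quartile means.

A command-line front-end wraps the same functions:

```sh
Rscript inst/cli/dietquality.R simulate --out-dir demo --n 100 --seed 1
Rscript inst/cli/dietquality.R score --ffq demo/ffq.csv \
    --covariates demo/covariates.csv --table demo/food_composition.csv \
    --open-section demo/open_section.csv --out-dir demo
Rscript inst/cli/dietquality.R analyze --scores demo/composites.csv \
    --covariates demo/covariates.csv --out-dir demo
Rscript inst/cli/dietquality.R power --n 100 --rho 0.3 --method simulation
```

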