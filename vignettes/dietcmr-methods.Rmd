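---
title: "Methods: dietary determinants and a healthy diet score for pediatric cardiometabolic risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary determinants and a healthy diet score for pediatric cardiometabolic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietcmr)
```

## The analysis this package implements

`dietcmr` implements a longitudinal analysis pattern for school-age cohorts
in which diet (3-day 24-hour recalls), anthropometry, blood pressure and
fasting blood chemistry are measured at a baseline visit and again about one
year later. The pipeline has five scientific stages:

1. **Diet features.** Recall items are mapped to 26 food groups, summed
   within day, averaged across the child's recall days, and expressed as
   energy-adjusted densities, `100 * grams/day / kcal/day` (grams per
   100 kcal). Energy adjustment removes the confounding of absolute intake
   with body size and total consumption. Children with implausible mean
   daily energy (below 300 or above 3500 kcal/day, strict inequalities), no
   dietary assessment, or no cardiometabolic measurement at all are
   excluded, with a per-reason log.
2. **Phenotypes.** BMI, mean arterial pressure (`DBP + 0.33 (SBP - DBP)`),
   the TG:HDL-C ratio and HOMA-IR (`insulin [uU/L] x glucose [mg/dL] / 405`,
   glucose converted from mmol/L at 18.0 mg/dL per mmol/L) are derived;
   fourteen measures are z-scored against sex- and integer-age strata of the
   baseline cohort; and the composite cardiometabolic risk score is
   `CMRS = z(WC) + z((SBP+DBP)/2) + z(glucose) - z(HDL-C) + z(TG)`.
   Change scores are follow-up minus baseline.
3. **Ranking.** The 26 baseline intake densities predict the one-year change
   in CMRS in three model families — elastic-net linear regression, a
   500-tree random forest, and gradient boosting — tuned by grid search
   under 5-fold cross-validation on a random half of the cohort and compared
   by R-squared on the held-out half. The winner's variable importances are
   floored at zero and normalized to percentage contributions summing
   to 100; the nine leading groups become the score's components.
4. **Healthy Diet Score (HDS).** Each leading group is dichotomized at its
   baseline median (zero-median groups split as consumers vs
   non-consumers) and assigned a direction by comparing adjusted mean
   change in CMRS between the low and high strata: `healthy_high` when high
   intake is favorable. The unweighted score awards one point per group on
   the favorable side (0-9). The weighted score prorates each group
   linearly between an intake of 0 and the baseline 80th percentile —
   rising for protective groups, falling for adverse ones — and sums the
   sub-scores weighted by the groups' normalized importance contributions.
   Definitions are frozen from baseline, serialized to JSON, and applied
   unchanged at follow-up or on an external cohort.
5. **Associations.** Changes in each of the 14 factors and in CMRS are
   regressed on HDS (six bands `<=3 ... >=8`, the continuous score, or its
   change) under three nested adjustment sets (M1: age, sex, baseline value
   of the outcome; M2: + intervention arm, grade, puberty, baseline BMI,
   MET, and baseline energy, fiber, vegetable, fruit, pork and nuts/legumes
   intakes; M3: + birthweight, breastfeeding, household income, parental
   BMI and education), always with a random intercept for school class.
   Trend tests across bands, Benjamini-Hochberg control at 5% across the
   outcome family (with the data-dependent cutoff reported), Bonferroni
   correction of all pairwise band contrasts, moderation (product-term)
   analysis, and control-arm sensitivity analyses complete the stage.

## The synthetic cohort generator

Real cohorts of this kind are rarely shareable, so the package ships a
generator whose outputs have the statistical structure the analysis
assumes, with known ground truth for every stage to recover.

**Diet.** Usual group intakes are zero-inflated lognormal: a latent
Gaussian per group decides consumption against the group's non-consumer
probability, and a second correlated latent sets the consumer's amount.
Both latents share an exchangeable correlation (default 0.3) within blocks
that mirror observed co-consumption patterns: a rice-based pattern (rice,
vegetables, poultry, seafood), a wheat-based pattern (wheat, refined
grains, fried foods, roots/tubers, fungi/algae), meat/eggs, dairy,
snacks/beverages, and other plant foods. Keeping the rice- and wheat-based
patterns in separate blocks matters: they carry planted effects of opposite
sign, and a single positively correlated cereal block would cancel the
weaker effects marginally, which is not what such cohorts show. Zero
inflation plus right skew is what recall data show: for many groups the SD
exceeds the mean, which a lognormal alone cannot produce. Marginal
parameters are calibrated to the g/100 kcal scale of recalls in 6-13
year-olds (e.g. rice ~7, seafood ~1.9, fungi/algae ~0.45 g/100 kcal, daily
energy ~1270 +/- 530 kcal). Three recall days per child are produced by
multiplying the usual intake by lognormal day factors; recalls give no
direct estimate of within-child day-to-day variation, so its coefficient of
variation is a free parameter defaulting to 0.30. Item-level energies are
prorated so each day's items sum exactly to the day's energy, keeping the
recorded records internally consistent with the child's usual
energy-adjusted intakes.

**Outcomes.** The baseline panel is drawn on physiological scales (glucose
~4.5 mmol/L, SBP ~100 mmHg, WC ~58 cm) with age and sex trends and a shared
adiposity latent that correlates waist, BMI, body fat, insulin, TG and
(negatively) HDL-C — and independently of diet, so the baseline composite
carries no diet signal. The one-year change in CMRS is constructed as

```
delta CMRS = sum_g effect[g] * standardized usual intake[g]
           + confounder effects + class random intercept + N(0, noise_sd^2)
```

split equally across the five score components on the z-scale of a
sex-by-age reference fitted to the generated baseline, then mapped back to
raw units and added to the baseline values together with per-outcome
one-year drifts (growth, tracking). The residual SD defaults to 1 so that a
planted `effect` of, say, -0.3 is both the raw regression slope of the
change score on the standardized intake and (to good approximation) a
-0.3 SD standardized effect — planted values can be read directly as effect
sizes. The class-level random intercept defaults to an intraclass
correlation of 0.05 so the cluster-adjustment machinery has something to
adjust for. Confounders (age, sex, intervention arm, activity, parental
education) act on the change score by default and can additionally be
coupled into the diet latents (`diet_confounding`), which is what makes the
nested adjustment models M1-M3 empirically distinguishable; the
`"paper-like"` fixture uses a coupling of 0.10.

**What the generator does not emulate.** Seasonal variation in diet,
item-level reporting error beyond the day factor, informative missingness
(missingness of blood measures is completely at random, ~2-3% per field
per visit), growth-reference (LMS-type) standardization, and any causal
effect of the intervention beyond a mean shift. Passing recovery tests on
these cohorts therefore demonstrates that the *machinery* is correct and
well calibrated — not that any particular real-world dietary effect exists.

## Numerical and design choices

* **Energy bounds as fixed kcal thresholds.** The plausibility filter is
  implemented as fixed 300/3500 kcal/day cutoffs applied as strict
  inequalities to the mean daily energy over the recall days (the analysis
  unit), and both thresholds are overridable.
* **Averaging before adjustment.** Grams and energy are averaged over days
  first and the 100 g/kcal ratio taken once. Adjusting per day and then
  averaging differs when energy varies day to day; the chosen order matches
  the definition of the density as mean daily grams per mean daily energy.
* **Stratum pooling.** Z-score strata are sex by integer age; strata with
  fewer than 20 children are pooled with the nearest age within sex (ties
  toward younger) until estimable. Zero-variance strata are an error, named
  by measure and stratum.
* **Baseline-frozen references and cutpoints.** The standardization
  reference, the median cutpoints and the 80th-percentile anchors are all
  fitted on baseline and reused at follow-up. A score or z-change computed
  against a drifting reference would conflate cohort drift with individual
  change.
* **Blood pressure component.** The composite's BP term is the z-score of
  the per-child mean of SBP and DBP standardized as one variable (the
  literal reading); averaging the two separate z-scores is available via
  `bp_component = "average_z"`.
* **HOMA-IR units.** The formula is stated in mg/dL while glucose is
  measured in mmol/L; the conversion is fixed at 18.0 mg/dL per mmol/L.
* **Percent body fat** is accepted as supplied (bioimpedance devices report
  it) or through a pluggable prediction function; no impedance-equation
  coefficients are hard-coded.
* **Median boundary rule.** A `healthy_high` point requires intake strictly
  above the median; a `healthy_low` point is awarded at or below it. A
  child at every median therefore scores exactly the number of
  `healthy_low` groups. For zero-median groups this reduces to the
  0 vs > 0 dichotomy.
* **Importance method.** Permutation importance on the held-out half is the
  default because it is model-agnostic and comparable across families;
  impurity importance is available for the forest. Negative permutation
  importances are floored at 0 before normalization, since contributions
  are reported as non-negative percentages. Contributions are normalized
  over all 26 predictors, not only the displayed leaders.
* **Grid search economics.** The forest grid is scored with 100-tree
  forests and the selected configuration refitted with the full 500 trees;
  cross-validated R-squared is insensitive to forest size well below that.
  Boosting and the elastic net are cheap enough to search at full size.
* **Ties.** Equal test R-squared breaks by the fixed family order
  (linear, forest, boosting); equal contributions break by the frozen
  group order.
* **Weights.** Importance weights of the nine selected groups are
  renormalized to sum to 1 so the weighted score lives on [0, 1]; raw
  percentage weighting (same ordering, different scale) is a flag.
* **Inference.** Confidence intervals and p-values use the normal
  approximation to the Wald statistic (the cohorts of interest have
  thousands of children and >100 classes). The trend test across bands uses
  the band index as a continuous term; the continuous-score slope is the
  equivalent test for non-banded exposures. With fewer than two clusters
  the mixed model falls back to a fixed-effects fit with a warning.
  Numeric nuisance covariates are unit-scaled inside the fit for
  conditioning; exposure and outcome scales are untouched.
* **The BH family** is the set of outcomes tested per exposure/model
  combination, and the procedure reports the data-dependent p-value cutoff
  alongside the decisions.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles and planted
truth, at sizes chosen to make Monte-Carlo error small relative to each
tolerance:

* exact agreement (1e-10) of energy adjustment, derived measures, CMRS and
  both scores with brute-force loop implementations on a 50-child fixture;
* empirical FDR of the step-up rule under 2000 replicate families of 50
  tests (40 null, 10 with 0.5 SD effects, 200 per arm) at most 5% + 1.5
  percentage points;
* recovery of at least eight of nine planted determinants in the winner's
  top nine in at least 80% of 20 cohorts of n = 3000;
* recovery of all nine planted directions in at least 90% of 20 cohorts of
  n = 3000;
* 95% CI coverage of a planted top-band effect between 93% and 97% over 500
  simulated cohorts of n = 2000, and trend-test type-I error between 3.5%
  and 6.5% over 1000 null cohorts;
* exact boundary behavior and monotonicity of both scores over 1000 random
  perturbations.

Generator marginals are checked at n = 10,000 on the generative scale
(non-consumer fraction within 0.02 absolute; consumer log-mean and log-SD
within 0.1, i.e. about 10% on the geometric mean), where Monte-Carlo error
is far below the tolerance; arithmetic means of heavily skewed zero-inflated
lognormals would carry sampling error of nearly the same size as the
tolerance itself at this n.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  seed = 1,
  sim = sim_config(n_children = 3000,
                   effect_vector = paper_like_effects(),
                   diet_confounding = 0.10))
res <- run_pipeline(cfg, out_dir = "run1")
res$importance$test_r2      # held-out R-squared per family
res$leading                 # the nine leading determinants
res$directions              # healthy_high / healthy_low per group
subset(res$assoc$results, outcome == "cmrs")
```

## Limitations

The association stage assumes a linear mixed model with a single
cluster level; pupils changing classes, survey weights, and imputation
beyond the explicit "Missing" category are out of scope. The ranking stage
treats the learners as exchangeable engines — it does not attempt to
disentangle the importance a food group borrows from correlated groups.
Scores built from internal medians are cohort-relative: applying a
serialized definition to a population with very different intake levels
changes the meaning of a "point".
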