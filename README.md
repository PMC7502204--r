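# dietcmr

Leading dietary determinants and a Healthy Diet Score (HDS) for changes in
cardiometabolic risk factors in children.

## The problem

Individual foods are weak, inconsistent predictors of cardiometabolic risk
(CMR) in children, and data-driven dietary patterns rarely transfer between
cohorts. `dietcmr` implements an alternative workflow for longitudinal
pediatric cohorts with repeated diet and clinical measurements: rank all
food groups by their importance for the one-year *change* in a composite
risk score using competing predictive model families, then distill the
leading groups into a simple, portable diet score and estimate its adjusted
associations with changes in individual risk factors.

It is intended for nutritional epidemiologists analyzing school-age cohort
or trial data with 24-hour recalls, and ships a synthetic cohort generator
with planted ground truth so every stage of the machinery can be validated
end to end.

## The score and the models

**Composite risk.** Fourteen measures (BMI, WC, percent body fat, SBP, DBP,
MAP, TC, HDL-C, LDL-C, TG, TG:HDL-C, fasting glucose, insulin, HOMA-IR) are
z-scored within sex × age strata of the baseline cohort. The composite
cardiometabolic risk score is

```
CMRS = z(WC) + z((SBP+DBP)/2) + z(glucose) − z(HDL-C) + z(TG)
```

and the analysis outcome is ΔCMRS = follow-up − baseline, with follow-up
standardized against the baseline-fitted reference.

**Ranking.** The 26 energy-adjusted food-group intakes (g/100 kcal/day,
`100 × g/day ÷ kcal/day`) at baseline predict ΔCMRS in three families —
elastic-net linear regression, a 500-tree random forest, and gradient
boosting — each grid-tuned by 5-fold cross-validation on a random half of
the cohort and compared by held-out R². The winner's permutation
importances are normalized to percentage contributions (summing to 100),
and the top nine groups become the score components.

**HDS.** One point per leading group on the favorable side of its baseline
median (strictly above for protective groups, at/below for adverse ones;
zero-median groups split consumers vs non-consumers), directions assigned
by comparing adjusted mean ΔCMRS between the low- and high-intake strata.
The weighted variant prorates each group linearly between zero intake and
the baseline 80th percentile and weights sub-scores by importance
contribution, giving a score in [0, 1]. Definitions are frozen from
baseline and serialize to JSON for reuse on external cohorts.

**Associations.** Changes in each factor are regressed on HDS bands
(`<=3 … >=8`), the continuous score, or its one-year change, under three
nested adjustment models (M1 ⊂ M2 ⊂ M3, from age/sex/baseline-value up to
household and parental characteristics), always with a random intercept for
school class. Benjamini–Hochberg step-up control at 5% is applied across
the outcome family (reporting the data-dependent p cutoff), Bonferroni
correction to all pairwise band contrasts, plus moderation and control-arm
sensitivity analyses.

## Worked example

Simulate a cohort of 3000 children with nine planted dietary effects
(protective: seafood, rice, red meat other than pork; adverse: refined
grains, fried foods, sugar-sweetened beverages, wheat, fungi/algae,
roots/tubers), then run the full pipeline:

```r
library(dietcmr)

cfg <- pipeline_config(
  seed = 1,
  sim = sim_config(n_children = 3000,
                   effect_vector = paper_like_effects(),
                   diet_confounding = 0.10))
res <- run_pipeline(cfg, out_dir = "run1")

round(res$importance$test_r2, 3)
#>   linear   forest boosting
#>    0.287    0.235    0.248

res$leading
#> [1] "refined_grains" "seafood" "fried_foods" "wheat" "ssb"
#> [6] "red_meat_other_than_pork" "fungi_algae" "rice" "roots_tubers"

round(res$importance$contributions[res$leading], 1)
#> refined_grains seafood fried_foods wheat  ssb red_meat... fungi  rice roots
#>           23.1    22.0        19.3  15.8 12.0        4.1   1.4   1.2   0.8
```

All nine planted groups are selected, and every direction is recovered
(`res$directions`): seafood, rice and red meat other than pork come out
`healthy_high`, the other six `healthy_low`. The adjusted association of
the score with ΔCMRS is a clean monotone gradient:

```r
subset(res$assoc$results, outcome == "cmrs")[, c("level", "beta", "ci_lo", "ci_hi", "n")]
#>   level   beta  ci_lo  ci_hi   n
#>   <=3    0.000  0.000  0.000 779
#>   4     -0.350 -0.486 -0.215 501
#>   5     -0.515 -0.647 -0.382 545
#>   6     -0.739 -0.885 -0.594 406
#>   7     -0.892 -1.072 -0.711 222
#>   >=8   -1.103 -1.375 -0.831  84
```

Children in the top score band improve their composite risk by about one
SD-sum more than the bottom band — the planted gradient, recovered through
the full recall → z-score → ranking → scoring → mixed-model chain.
Artifacts (profiles, reference, importance, score definition, results,
manifest) are written under `run1/`.

## Documentation

See `vignettes/dietcmr-methods.Rmd` for the model assumptions, every
numerical choice (stratum pooling, boundary rules, tie-breaks, grid
design), what the synthetic generator does and does not emulate, and the
validation strategy with its problem sizes.
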