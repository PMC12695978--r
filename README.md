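# isoshape

Does social isolation harm health only beyond the conventional cutoff, or
along the whole contact spectrum? The answer decides between a high-risk
prevention strategy (target the isolated) and a population strategy (shift
everyone's exposure). `isoshape` implements an analysis pipeline that puts
three hypotheses about the LSNS-6 (Lubben Social Network Scale, 0–30,
higher = more contact, scores < 12 = socially isolated) on an equal footing:

* **A** — a linear effect across the whole score range,
* **B** — an effect everywhere, steeper below the cutoff,
* **C** — an effect only below the cutoff,

and quantifies how much of the total effect is borne by people *not*
classified as isolated.

## What's in the package

* **A self-contained penalized additive mixed model engine** —
  `fit_gamm()` fits `g(E[y]) = covariates + s(age) + s(LSNS) + (1 | id)`
  for gaussian, Poisson and gamma families: P-spline smooths (cubic
  B-splines, second-order difference penalty), penalized IRLS, GCV/UBRE
  smoothing-parameter selection, and participant random intercepts as a
  ridge-penalized block absorbed analytically (thousands of participants
  fit in well under a second). Term-level Wald tests, BIC, partial effects
  with pointwise bands, concurvity, VIFs and an oversmoothing check with
  `k = 20` escalation round out the engine.
* **Smooth-vs-linear adjudication** — `compare_models()` (deviance test +
  BIC, conjunctive preference rule) and `classify_shape()` (delta-method
  CIs on mean gradients below/above the cutoff) turn fits into an A/B/C
  verdict.
* **The effect-share statistic** — `effect_share()` multiplies per-score
  |local gradient| by the empirical score frequency and splits the total at
  the cutoff: a linear fit puts the below-cutoff share exactly at the
  isolation prevalence (~20%); a threshold-only fit puts it at 100%.
* **A synthetic cohort simulator** — `sample_cohort()` emulates the study
  structure the analysis assumes: two waves 6.5 years apart, 55% retention,
  53% female, a rounded truncated-normal LSNS marginal (mean 16.5, SD 5.7,
  ~19% below 12), participant random intercepts, configurable ground-truth
  shapes per outcome, plus the covariates and raw cognitive subtests the
  measurement formulas consume.
* **Measurement derivations** — cognitive composites, ICV-adjusted
  hippocampal volume, OECD-equivalised income and its banded score, SES
  score/quintiles/rebalancing weights, hypertension/diabetes
  dichotomizations with plausibility filters, asinh CESD, the negate-shift
  transform for gamma outcomes — and a lean chained-equations multiple
  imputation (`impute_chained()`, per-imputation reporting, no pooling).
* **Orchestration** — `run_outcome()`, `fdr_family()` (BH within the
  cognitive-aging family), `stratified_run()` sensitivity refits,
  `run_power()` for the nonlinearity-detection power study, and
  `run_pipeline()` / `summarize_pipeline()` for the end-to-end artifact
  bundle. `tidy()`, `glance()` and `autoplot()` methods keep everything
  pipe-friendly.

## Worked example

Simulate a cohort whose outcome truly follows hypothesis B (slope 0.05 per
LSNS point above the cutoff, 0.25 below, unit residual SD), fit the full
and base models, and adjudicate the shape:

```r
library(isoshape)

cfg <- cohort_config(n_participants = 3000, seed = 42)
tab <- sample_cohort(cfg, shapes = list(y = shape_spec("B")))

full <- fit_gamm(tab, model_spec("y", parametric = "gender",
                                 smooths = list(smooth_spec("age"),
                                                smooth_spec("lsns"))))
base <- fit_gamm(tab, model_spec("y", parametric = c("gender", "lsns"),
                                 smooths = list(smooth_spec("age"))))
full
#> <gamm_fit> y ~ gender + s(age) + s(lsns) + (1 | id)
#>   family gaussian(identity), n = 4640, edf = 800.28, deviance = 3864, BIC = 1.908e+04

cmp <- compare_models(full, base)
cmp
#> # A tibble: 1 x 4
#>          p delta_bic    df preferred
#>      <dbl>     <dbl> <dbl> <chr>
#> 1 7.76e-22      468.   0.5 full

pe <- partial_effect(full, "lsns", grid = 0:30)
classify_shape(cmp, pe)
#> # A tibble: 1 x 10
#>   hypothesis grad_below se_below ci_below_lo ci_below_hi grad_above se_above ...
#> 1 B               0.235   0.0196       0.196       0.273     0.0620  0.00862

glance(effect_share(full))
#> # A tibble: 1 x 2
#>   share_below share_above
#> 1       0.480       0.520
```

The comparison rejects linearity (p ≈ 8e-22 with a lower BIC for the full
model), the verdict is **B** with the below-cutoff mean gradient (0.235)
recovering the true 0.25 and the above-cutoff gradient (0.062) the true
0.05, and the effect share shows the isolated fifth of the population
bearing 48% of the total effect — between the 20% a linear effect would
imply and the 100% of a pure threshold. `autoplot(pe, cutoff = 12)` draws
the partial effect with its band; `autoplot(effect_share(full))` draws the
per-score decomposition.

Under a linear truth (`shape_spec("A")`) the same pipeline returns verdict
A with the share above the cutoff close to 80% — the empirical core of the
population-strategy argument.

## Documentation

The methods vignette (`vignettes/shape-analysis.Rmd`) describes the model,
the smoothing-parameter selection, the shape-classification rule, the
effect-share statistic, what the synthetic cohort does and does not
emulate, and every numerical choice with its default.
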