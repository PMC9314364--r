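# rrscore

Supervised reduced-rank scoring of Likert questionnaires.

## The problem

Classical personality inventories are scored with fixed unit weights: a
100-item five-factor questionnaire is collapsed to five scale scores by
averaging each factor's 20 items (after reverse coding the negatively keyed
ones). Those five numbers were designed to *describe* personality reliably,
not to *predict* life outcomes — typical item-outcome correlations of
0.1–0.3 leave explained variances in the single digits.

`rrscore` implements the alternative: learn the five-dimensional summary
**from the outcomes**. Given an item matrix `X` (n × p, Likert 1–5) and an
outcome battery `Y` (n × q), reduced-rank regression (RRR) solves

```
Ĉ = argmin_C || Y − X C ||²   subject to  rank(C) = r
```

(Frobenius norm, X and Y centred and scaled). The solution factorises as
`C = B Aᵀ` with `B` (p × r) and `A` (q × r), so `X̃ = X B` is a new r-dimensional
representation of each respondent optimised to predict the whole outcome
battery at once, and `Ŷ = (X B̂) Âᵀ`. The closed form is exact: `A` holds the
top-r right singular vectors of the unconstrained fitted values `X C_ols` and
`B = C_ols A`; a multi-start alternating-least-squares oracle is included to
verify global optimality in the tests.

Around that core, the package provides the full evaluation apparatus such a
claim needs:

* **Two-stage cross-validation** (`two_stage_cv()`, `run_study()`): the
  projection `B̂` is learned on a training cohort; on an independent test
  cohort the per-outcome coefficients are re-learned on ¾ of the
  participants and R²/MAE measured on the held-out ¼, iterated fourfold
  (600/200 under the default 800-participant test cohort). Baselines:
  unit-weight scale scores (`scales`) and principal-component regression
  (`pcr`); a frozen projection can be transferred to new samples and new
  outcomes (`study_mode = "transfer"`).
* **Paired inference** (`paired_error_ttest()`, `bh_fdr()`): per-participant
  absolute prediction errors are paired across models, compared by
  one-sample t-test, and controlled by Benjamini–Hochberg FDR.
* **Psychometric diagnostics**: split-half reproducibility of the learned
  dimensions, test–retest reliability, exhaustive signed-permutation
  alignment of latent spaces (`align_signed_permutation()`, 3,840 candidates
  at r = 5), and a cosine-similarity convergence/divergence analysis with
  Hedges' g (`divergence_analysis()`).
* **Sample-size planning** (`corridor_coverage()`): corridor-of-stability
  simulation for running correlations.
* **A synthetic-cohort generator** (`generator_spec()`,
  `generate_cohort()`): Likert items driven by latent traits through a
  loading matrix and fixed thresholds, outcomes linear in the latents with
  population R² calibrated to the realistic 1–9% band, and a retest
  administration with controllable latent stability. Every downstream stage
  is testable against known ground truth.

Fitted objects and reports are tidyverse-friendly: `tidy()`, `glance()` and
`autoplot()` methods are provided, reports are tibbles, and cohorts, models
and scale keys round-trip through plain CSV/JSON.

## Worked example

```r
library(rrscore)

spec   <- generator_spec(n_participants = 10800, seed = 42)
cfg    <- study_config(generator = spec, n_test = 800, r = 5, n_folds = 4, seed = 42)
result <- run_study(cfg)
result
#> <study_result> study1 mode (seed 42)
#> <evaluation_report> 10 outcomes x rrr/scales/pcr, 4-fold CV on n = 800
#> # A tibble: 3 × 3
#>   model  mean_r2 mean_mae
#>   <chr>    <dbl>    <dbl>
#> 1 pcr     0.0294    0.814
#> 2 rrr     0.0281    0.815
#> 3 scales  0.0295    0.814
#>   split-half reproducibility (mean r): 0.646
#>   test-retest reliability (mean r): rrr 0.699, scales 0.767
#>   divergence Hedges' g: 0.111
```

Reading the numbers: each model's out-of-sample R² is averaged over the ten
outcomes and four holdout folds — here all three representations land near
3%, as expected when the outcomes are driven by the same latent traits that
dominate item variance (population outcome R² in this generator spans
1–9%, and Likert discretisation plus finite samples attenuate it). The
supervised representation separates from the unsupervised baselines
precisely when the predictive signal hides in low-variance item directions —
`spec_supervised_advantage()` builds that scenario, where the `rrr` holdout
R² beats `pcr` by ~0.18 on average. Reliability ~0.7 per dimension reflects
the generator's latent retest stability of 0.8 after item noise; the
divergence g near zero says the learned space and the scale-score space
coincide in this synthetic world — on real data the substantive question is
whether g is large.

`result$evaluation$comparisons` holds the per-outcome paired t-tests with
FDR flags, `tidy(result$model)` the item loadings of each learned dimension,
and `autoplot(result$evaluation)` the R²-by-outcome comparison figure.

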