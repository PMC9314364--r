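---
title: "Supervised reduced-rank scoring: model, evaluation design, and simulation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised reduced-rank scoring: model, evaluation design, and simulation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrscore)
```

## The model

A questionnaire with `p` Likert items is usually summarised by a handful of
unit-weight scale scores. `rrscore` instead learns an `r`-dimensional summary
that is optimal for predicting a battery of `q` outcome variables. With
`X` (`n x p`) and `Y` (`n x q`) centred and scaled, reduced-rank regression
solves

$$\hat C = \arg\min_C \| Y - XC \|_F^2 \quad \text{s.t.}\quad \mathrm{rank}(C) = r,$$

factorised as $C = BA^\top$ with $B \in \mathbb{R}^{p\times r}$ and
$A \in \mathbb{R}^{q\times r}$. The respondent-level representation is
$\tilde X = XB$, and predictions are $\hat Y = (X\hat B)\hat A^\top$.

`fit_rrr()` uses the classical closed form: let $C_{\mathrm{ols}}$ be the
unconstrained least-squares solution (Moore–Penrose pseudoinverse when
$X^\top X$ is singular, with a logged warning; singular values below
$10^{-10}$ of the largest are treated as zero). Then $A$ collects the top-$r$
right singular vectors of the fitted values $X C_{\mathrm{ols}}$ and
$B = C_{\mathrm{ols}} A$. This attains the global rank-$r$ minimum; the test
suite verifies it against `rrr_brute_oracle()`, an independent multi-start
alternating-least-squares solver, and against large sets of random rank-$r$
competitors.

Identifiability: a rank-constrained factorisation is only defined up to a
signed permutation (and, for the loss, any invertible mixing) of its columns.
We fix columns in decreasing order of the fitted-value singular values and
flip each column's sign so its largest-magnitude item loading is positive.
Predictions are invariant to this choice; it only makes stored models
reproducible. The error metric is the plain (unweighted) Frobenius norm — no
inverse-covariance weighting — and no intercepts are carried because both
blocks are centred; predictions are mapped back to the outcome scale at the
end. Scores $\tilde X$ are used as produced by $XB$, without per-column
rescaling, before the outcome coefficients are learned.

Two baselines share the same interface: unit-weight scale scoring
(`score_scales()` with a `scale_key`: per-factor means after reverse coding
`x -> min + max - x`) and principal-component regression (`fit_pcr()`:
leading `r` principal axes of the standardised items, learned on training
data only, then per-outcome regression on the component scores).

## The two-stage evaluation design

The question the package is built to answer — does a supervised 5-dimensional
summary predict better out of sample than the classical scale scores? — needs
care about what is "known" when. `two_stage_cv()` therefore separates:

* **Stage 1** learns the representation (the projection $\hat B$, the
  principal axes, or nothing for fixed scale keys) on a *training cohort*.
* **Stage 2** treats the representation as known and evaluates on an
  independent *test cohort* with `n_folds`-fold cross-validation: outcome
  coefficients are re-learned per fold on the in-fold part and R² / mean
  absolute error are measured on the holdout. Under the default fourfold
  scheme with an 800-participant test cohort this is the 600/200 split. Fold
  assignment is a seeded shuffle with remainders spread one per fold; every
  test participant is held out exactly once, so absolute errors are paired
  across models.

Design choices that the underlying procedure leaves open, and how they are
resolved here:

* **R² convention.** Out-of-sample R² uses the *holdout* mean in the total
  sum of squares (the stricter convention; an external centre can be passed
  to `r_squared()`).
* **Standardisation never leaks.** Means/sds are fitted on training data
  and applied to held-out data (`fit_standardizer()` / `apply_standardizer()`,
  `n − 1` denominator). Whether the original procedure standardised per fold
  or globally is unstated; train-fitted/test-applied avoids optimistic bias.
* **Paired tests.** Per-outcome model comparisons pool each participant's
  single holdout error across the folds and run a two-sided one-sample
  t-test on the differences of absolute errors. Degenerate inputs follow
  documented conventions (all-zero differences: t = 0, p = 1; zero variance
  with nonzero mean: t = ±Inf, p = 0) rather than erroring mid-pipeline.
* **FDR family.** Benjamini–Hochberg is applied across the outcomes within
  one model pair (the per-study family), at α = 0.05.
* **Percent change.** Both the percent R² change and the percent MAE change
  between models are reported, since "percent improvement" is ambiguous
  between the two.
* **Transfer designs.** For the design where a previously learned projection
  is evaluated on a new sample with new outcomes, `cv_scheme()` accepts a
  pre-fitted model (`models = "external"`); stage 1 is skipped and only the
  per-fold outcome coefficients are learned on the new data.

## Psychometric diagnostics

* **Reproducibility** (`split_half_reproducibility()`): fit $B$ on two
  disjoint cohorts, project a common held-out evaluation set with both, and
  correlate per dimension. Which participants receive both projections is
  unspecified in the underlying procedure; a common held-out set is the
  cleanest choice. Dimensions are matched by exhaustive signed-permutation
  alignment first, because column order/sign is arbitrary.
* **Reliability** (`test_retest_reliability()`): per-dimension Pearson
  correlation of projected scores across two administrations.
* **Alignment** (`align_signed_permutation()`): exhaustive search over all
  $2^r r!$ signed column permutations (3,840 at r = 5), so the reported
  "maximal possible similarity" is globally maximal, not heuristic. The
  search reduces to a per-column match matrix, but tests verify it against a
  full from-scratch enumeration. For r > 6 a documented greedy fallback
  (`align_greedy()`) is provided.
* **Divergence** (`divergence_analysis()`): per-participant cosine
  similarity within each representation across two administrations
  (convergence) versus between representations (divergence), summarised by
  Hedges' g — pooled-SD Cohen's d times the small-sample correction
  $J = 1 - 3/(4(n_1+n_2-2)-1)$ — of the smallest within-vs-between contrast.
  Two open choices are resolved as follows. (1) Score matrices are
  standardised per dimension before the cosine, so bounded 1–5 scale scores
  and unbounded projection scores contribute comparable geometry
  (switchable). (2) The headline between-measure comparison crosses
  administrations (measure 1 at time 1 vs measure 2 at time 2 and vice
  versa). This makes the diagnostic *calibrated*: if the two representations
  are identical, between- and within-measure similarities have exactly the
  same distribution and g = 0. Same-occasion comparisons share occasion
  variance (the same latent state and the same response noise enter both
  score vectors), so they are inflated even under identity — they are
  reported alongside (`between_same`) and selectable via
  `between_occasion = "same"`.
* **Sample-size planning** (`corridor_coverage()`): fraction of simulated
  sequential-sampling trajectories whose running Pearson correlation stays
  within ±w of the true ρ from `n_start` through `n_max`. Pointwise coverage
  is validated against the Fisher-z normal approximation. The package's own
  simulation puts coverage for ρ = 0.1, w = 0.1 over n ∈ [470, 1000] at
  about 95% (the acceptance script recomputes this number; across many
  seeds it averages a couple of tenths of a point below 95, so individual
  10,000-trajectory estimates fall on either side of it).

## What the synthetic generator emulates — and what it does not

Real item-outcome data of this kind cannot be redistributed, so the
generator provides cohorts with known ground truth. Per participant, latent
traits $Z \sim N(0, I_k)$ (a Cholesky option allows correlated traits);
continuous item scores are $\Lambda Z + \varepsilon$; fixed thresholds
discretise them to 1–5; outcomes are $W Z + \eta$; a retest administration
redraws $Z_2 = sZ_1 + \sqrt{1-s^2}\,\epsilon$ and regenerates items, so the
test–retest attenuation is controllable through one number.

The defaults are the package's fixed simulation conditions:

* **Items:** p = 100 in five 20-item blocks, |loading| = 1 per item on its
  block's latent, the last 6 items of each block negatively keyed (about
  30% reverse-coded items, as in real five-factor inventories), item noise
  sd 1 — items are half signal, half noise.
* **Thresholds:** at the 20/40/60/80% quantiles of the continuous item
  score's distribution, so the five categories are balanced. A graded-
  response-style simplification: one fixed set of cutpoints for all items.
* **Outcomes:** q = 10, each driven by one latent, with population R²
  spaced evenly from 1% to 9% — the realistic effect-size band for
  single personality-outcome associations. `pop_outcome_r2()` exposes the
  closed form $\mathrm{rowSS}(W)/(\mathrm{rowSS}(W) + \sigma^2)$.
* **Retest:** latent stability 0.8, which with item noise yields observed
  score reliabilities around 0.7 — the realistic range for questionnaire
  dimensions.
* **`Z_true` is carried in the cohort but read only by tests and
  diagnostics; no fitting path touches it.**

Two purpose-built scenarios depart from the defaults:

* `spec_supervised_advantage()`: six latents — five high-variance nuisance
  blocks (18 items each) and one low-variance latent measured by 10 items
  with loading 0.4 — with all outcomes driven by the low-variance latent
  (population R² 0.3). This is the regime where supervised reduction must
  beat unsupervised components: the leading principal components spend
  their capacity on the nuisance blocks, while the rank-constrained fit
  targets the predictive direction. The test suite requires the supervised
  holdout R² to win in at least 95 of 100 replicates
  (n_train = 2,000 / n_test = 800 each).
* The subspace-recovery experiment generates outcomes *directly* as a true
  rank-5 linear map of the standardised items,
  $Y = X_s B_0 A_0^\top + \eta$ with orthonormal $B_0$, at moderate noise
  (outcome R² ≈ 0.75). The largest principal angle between
  $\mathrm{span}(\hat B)$ and $\mathrm{span}(B_0)$ must fall below 10° at
  n = 50,000 and decrease over n ∈ {5,000; 20,000; 50,000}. Item-level truth
  is used here because latent-driven outcomes define their predictive
  subspace only up to Likert-discretisation distortion, which would blur a
  geometric recovery criterion.

What the generator does **not** emulate: the specific content or
distributional quirks of real outcome instruments (skewed count outcomes
such as online-network sizes, test-score ceilings), item-specific threshold
sets, acquiescence or other response styles, and missing data (cohorts are
complete-responder by construction). Passing tests therefore demonstrate the
*procedural* correctness and the qualitative behaviour of the method under a
plausible latent-trait world, not that any particular real-data effect size
will be reproduced.

## Numerical and degenerate-input conventions

* Constant columns are rejected at standardisation time with the column
  named; degenerate projections (zero-variance score columns) abort the
  reproducibility analysis.
* Rank-deficient designs take the pseudoinverse path with a machine-readable
  warning; no ridge term is added.
* Zero score vectors are excluded (with a logged count) from cosine
  similarity summaries rather than propagating NaN.
* Ties in the alignment search resolve to the first candidate in a fixed
  lexicographic enumeration, making results deterministic.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  cohorts, fold assignments and simulations are bit-reproducible; a study
  run writes a manifest (seed, configuration hash, package version) and
  identical configurations produce byte-identical result files.
* Serialisation writes doubles in shortest round-trip form (CSV) or as
  17-significant-digit strings (JSON header fields) and parses them with
  `strtod`, so saved models and cohorts restore bit-exactly.

## Problem sizes used by the checks

The test suite runs the optimality check on 100 random small instances
(n = 200, p ≤ 8, q ≤ 4, r ≤ 3, 1,000 random competitors each), the recovery
experiment at n up to 50,000, the supervised-advantage comparison on 100
replicates of 2,800 participants, a study-shaped run at n_train = 20,000 /
n_test = 800, t-test calibration on 1,000 null simulations, and the
corridor simulation on 10,000 trajectories; split-half reproducibility is
exercised at 100,000 participants per half. These sizes keep every
property's Monte-Carlo error well inside its assertion margin.

## Known limitations

* The exhaustive alignment is factorial in r; r ≤ 6 is enforced with a
  greedy fallback beyond.
* The generator's Gaussian outcomes cannot represent heavily skewed
  real-world outcomes; divergence and reliability values quoted from real
  studies are not reproducible from synthetic cohorts.
* No sparse or regularised rank-constrained variants are provided, and no
  nonlinear embeddings; the estimator is the plain least-squares one.
* Hedges' g here is the standard pooled-SD form with the J correction;
  published values computed with other pooling conventions can differ in
  the second decimal.
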