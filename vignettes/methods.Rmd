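---
title: "Methods: compositional time-use and diet equivalence modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional time-use and diet equivalence modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiv24)
```

This vignette is the package's own account of its statistical machinery:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical decisions that a maintainer would otherwise
have to reverse-engineer from the code.

## 1. Data model

A person-day is described by

* seven time-use durations (min/day) that close to 1440: sleep, self-care,
  screen time, quiet time, physical activity, school-related,
  domestic/social;
* three diet serving scores built from nine previous-day frequency items
  coded 0–3 ("not at all" to "more than twice"), each instance counted as
  one serve: fruit and vegetables (3 items, 0–9), discretionary foods
  (4 items, 0–12), sugar-sweetened beverages (2 items, 0–6);
* the PedsQL teen physical-functioning scale: eight items coded 0–4
  (higher = more of a problem), scored as `25 * (4 - mean(items))` onto
  0–100 (higher = better), missing when five or more items are missing;
* covariates: age (years), sex (0/1, 1 = female), socioeconomic position
  (z-score).

Scoring conventions worth making explicit: a missing diet item makes its
food-group score missing and the record drops from the analytic sample
(complete-case flow); the PedsQL mapping is the standard linear reverse
transform, which is the unique linear map consistent with both published
endpoints (all-0 items → 100, all-4 items → 0).

## 2. Compositional preprocessing

**Zero replacement.** Time-use diaries contain structural zeros (a
behaviour not performed on the diary day) in every behaviour except sleep
and self-care. Because log-ratios require strictly positive parts, zeros
are replaced below a 10-min cap — interpretable as the resolution below
which the diary cannot distinguish "none" from "a little". The default
`lrEM` routine initialises zeros at `0.65 * cap`, then iterates: express
each row in additive log-ratio coordinates against a zero-free denominator
part, regress each censored coordinate on the others over uncensored rows,
re-impute the censored cells from the predictions (capped at 10 min), and
re-close. Convergence is declared when the largest relative change of any
imputed value falls below `1e-6` (at most 50 iterations; in practice a
handful). Re-closure is *cap-aware*: the imputed cells are pinned at or
below the cap and the observed parts absorb the slack proportionally, so
observed within-row ratios are preserved exactly and rows sum to exactly
1440. A simple multiplicative replacement (`method = "multiplicative"`,
fixed `0.65 * cap` imputation) is provided as a transparent fallback and as
the independent oracle in the test suite.

**ilr coordinates.** The default basis is the pivot (Helmert-type)
sequential binary partition in the canonical part order: coordinate *i*
balances part *i* against the geometric mean of the later parts. The choice
is immaterial for every reported quantity — fitted values, predictions,
residual sums of squares, the block F-test and standardised coefficients
are all invariant to rotation of the coordinate system — and the test suite
asserts this at `1e-8` for permuted part orders. The basis matters only for
interpreting individual `z` coefficients, which the package never reports
as headline results.

**Reference profile.** The "average day" that anchors the equivalence
engine is the closed geometric mean of the preprocessed compositions,
rounded onto the 10-min grid. Naive per-part rounding does not preserve the
1440 total (the published study's printed means round to 1450), so the
package uses largest-remainder apportionment: floor each 10-min quota,
then hand the remaining 10-min units to the parts with the largest
fractional remainders, breaking ties by part order. This reproduces the
published reference day (740, 130, 160, 170, 50, 130, 60) exactly from the
published compositional mean (741, 125, 163, 175, 50, 129, 58). Diet
references are means rounded half-away-from-zero to whole serves.

## 3. The outcome model

The physical-functioning score is bounded and left-skewed, so a BoxCox
transform is applied before OLS. The exponent is estimated by profile
likelihood on the full regression design, maximised on [−5, 5] by a coarse
grid (101 points) followed by golden-section refinement; the profile is
smooth and unimodal in all realistic cases, and the estimate matches the
standard `MASS::boxcox` grid oracle to two decimals in the tests. Because a
0–100 score can be exactly zero, a unit shift is applied automatically
whenever `min(y) = 0` and recorded in the fit; predictions undo it.

The linear model regresses the transformed outcome on the six ilr
coordinates, the three diet scores and the covariates (13 parameters). The
fit errors informatively on rank-deficient designs (naming the collinear
columns) and warns on saturated fits (`df_residual = 0`). Inference
reported:

* **Compositional block F-test** — partial F comparing the full model to
  the model without all six ilr coordinates; this is the only way to test
  "is the 24-h composition associated with the outcome" that does not
  depend on the basis.
* **Standardised betas** for diet: `b * sd(x) / sd(t)` on the analytic
  sample, with the coefficient's own t-test p-value. Standardisation uses
  the *transformed* outcome SD, since that is the scale on which the model
  is linear.
* **Sex-interaction screen** — partial F-tests of sex × block terms, the
  composition as one six-degree-of-freedom block and each diet score
  singly. Stratification is never performed; the screen only justifies
  pooling.

## 4. The equivalence engine

The fitted model becomes a prediction engine. From the reference profile,
every zero-sum integer reallocation on the 10-min grid with each behaviour
within ±30 min is enumerated (60,691 vectors for seven parts — the grid is
grown column-wise with feasibility pruning and is deterministic and
lexicographic, so artifacts are byte-stable), and crossed with every diet
change on the 0.5-serve grid within ±1.5 serves that keeps each score
non-negative and within its questionnaire maximum (294 triples at the
default reference; the SSB floor at −1 serve emerges from the non-negativity
rule, not a special case). The ±30 min bound is per-behaviour (a Chebyshev
radius): that is how the grid itself is defined, and a Euclidean ball would
exclude combinations with several simultaneous ±30 changes that the study
design explicitly includes.

For each combination the perturbed day is re-expressed in ilr coordinates,
predicted with covariates fixed (age and SEP at the analytic-sample mean,
sex at its mode, ties broken toward female in a 50% female sample), and the
difference from the reference prediction is taken **after back-transforming
both predictions to the 0–100 scale**, because target differences are
stated in scale points. On the transformed scale the model is exactly
additive in the time and diet contributions, which the engine exploits: the
full difference surface is an outer sum back-transformed in chunks, making
the ~17.8 million predictions a few seconds' work; a scalar per-combination
path (`predict_difference()`) exists for verification and spot use.

**Banding.** Combinations are assigned to a target band when their
predicted difference is within `tolerance` of a target (±0.5 to ±2.5 by
0.5). The study reports options "associated with" discrete differences
without stating a rule; the package's default tolerance of 0.25 — half the
target spacing — is the unique choice that makes the bands disjoint and
exhaustive over the covered range. The constructor rejects tolerances that
would overlap bands. The alternative (rounding to the nearest 0.5) is the
same rule stated differently; a genuinely different rule (e.g. a narrower
window) would shrink all band counts proportionally without changing their
qualitative pattern.

**Sequential filtering.** `selection_state()` holds a band's rows;
`select_option()` intersects with one (behaviour, change) choice at a time.
The deltas offered for an unselected behaviour are exactly the distinct
values in the remaining subset, so a user can never paint themselves into
an empty set, and filtering is order-invariant (set intersection commutes)
— both properties are tested exhaustively on a small table.

## 5. The synthetic cohort generator

The generator exists so that every stage has a ground truth. Defaults are
fixed once to emulate the published sample summaries and are not tuned per
analysis:

* **Time use**: ilr coordinates drawn multivariate-normal around the ilr
  image of the published compositional mean (741, 125, 163, 175, 50, 129,
  58). Variation is parameterised by per-part log-scale SDs, giving the ilr
  covariance `V diag(s²) V'`; the defaults (0.11, 0.50, 0.85, 0.65, 1.20,
  1.15, 1.20) were calibrated once so the arithmetic SDs of the six
  non-dominant behaviours land within ±30% of the published SDs. Sleep's
  arithmetic SD cannot be matched under this independence structure: the
  dominant part absorbs the closure-complement of all other parts'
  variance, so its simulated SD is roughly double the published one. This
  is a known, accepted limitation of the diagonal choice (matching it would
  require structured negative dependence among the non-sleep parts, which
  nothing downstream needs).
* **Zeros** are injected per behaviour with small probabilities (0.5–3%,
  none for sleep/self-care), donating the zeroed minutes to the person's
  largest remaining behaviour so the day still closes to 1440. Rates are
  deliberately modest: the convergence check on the generator (geometric
  mean of the clean rows within 5 min/part of the target) and the
  parameter-recovery tests both assume zeros are a perturbation, not a
  regime.
* **Diet items** are independent categorical draws with probabilities set
  so the score means land at 3.69, 2.0 and 0.6 serves (published: 3.7,
  2.0, 0.6).
* **Outcome**: latent transformed score `t = X β_true + N(0, σ²)` with
  λ = 2, σ = 450 on the transformed scale, built through the *same*
  preprocessing chain the analysis uses (zero replacement, ilr), then
  back-transformed, clamped to [0, 100] and quantised to eight item
  responses whose mean reproduces the score at the item grid's resolution
  (25/8 ≈ 3.1 points). The time-use effect is specified as an
  interpretable log-contrast (per-part coefficients on log-minutes summing
  to zero, default favouring physical activity and sleep and penalising
  screen, quiet and self-care time) and converted internally to ilr
  coefficients; the intercept is derived so the expected score at the mean
  profile is 89 points. These effect sizes were chosen so the best feasible
  combined change predicts roughly +2.5 points — the study's largest
  reported band — while diet standardised betas land in the published
  0.04–0.08 magnitude range.

What the generator does **not** emulate: the sample's ceiling effect at
100 (the default σ keeps censoring below ~3% so that OLS recovery is
clean; the real scale's SD of 12.8 implies heavy ceiling mass), day-type
(school vs non-school) structure, correlated diet items, and any
covariance between time use, diet and covariates beyond what the outcome
model induces. Consequently a green test suite demonstrates that the
*machinery* is correct under the stated generative model, not that the
published effect estimates are reproduced — those require the restricted
cohort data.

## 6. Numerical choices and degenerate inputs

* Row closure tolerance for incoming durations: 0.5 min (diaries are
  integer-valued); internal closure is exact to floating point, and grid
  arithmetic uses integers so perturbed days sum to exactly 1440.
* `largest_remainder_round` floors quotas with a `1e-9` guard against
  floating-point quota undershoot; remainder ties resolve by position
  (first part wins), which is what reproduces the published reference day.
* BoxCox: |λ| < 1e-12 is treated as the log case; `boxcox_inverse` refuses
  values outside the transform's range rather than returning complex or
  NaN results; constant outcomes are rejected (degenerate likelihood).
* The lrEM denominator part is the first zero-free column; if an imputation
  regression is under-determined (too few uncensored rows) it falls back to
  the intercept-only prediction for that coordinate.
* Option-table row order is lexicographic in (time vector, diet triple),
  making every artifact byte-stable for a fixed configuration and seed.
* YAML configs reject unknown keys outright, and YAML-1.1 boolean literals
  are kept verbatim so the cohort-size key `n` is not parsed as `no`.

## 7. Problem sizes used by the test suite

The suite validates calibration-sensitive claims at sizes chosen to keep
the full run around two minutes: single-cohort parameter recovery at
n = 2000 (the study's analytic scale), 95% CI coverage pooled over 200
replicate cohorts of n = 2000, the block-test null level over 1500
replicate cohorts of n = 400 (binomial SE ≈ 0.006 against the 0.03–0.07
acceptance band), power at n = 2000 over 40 replicates, and the full
60,691 × 294 enumeration verified cell-for-cell against an independent
scalar code path. The band-stability check (fitted vs generating model)
runs at n = 10,000 with σ = 20: a size derived beforehand from the
quantisation noise floor, since band edges 0.5 points apart flip at a rate
of roughly four times the mean prediction error.

## 8. Known limitations

Cross-sectional prediction only — the equivalence sets are model
extrapolations from the sample average, not causal claims; changes are
anchored at the reference profile, so conclusions do not transfer to
individuals far from the average day; the linear diet terms extrapolate
outside the enumerated ±1.5-serve window; and the generator's independence
assumptions understate the dependence structure of real diaries, so
real-data standard errors will differ from the simulated ones.
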