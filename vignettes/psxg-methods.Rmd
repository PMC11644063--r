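---
title: "Methods: a post-shot expected-goals model for goalkeeping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a post-shot expected-goals model for goalkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psxg)
```

## The estimation problem

The unit of analysis is a *routine*: a pre-programmed shot that many
players face many times. For each routine we observe its ball-flight
metadata and the proportion of plays that ended in a goal. Because the
same flight is replayed, the natural target is this per-routine goal
proportion rather than a per-play binary label — a classifier trained on
duplicated feature rows with conflicting labels would collapse to the same
score anyway, while the proportion is a direct, denoised estimate of the
quantity we want: the probability that this flight beats a typical keeper.

Proportions from few plays are noisy, so routines with fewer than
`min_plays = 100` plays (inclusive) are excluded from *fitting*; the
fitted model still scores them at prediction time (`predict_all()`).

## Features

Three features summarize a flight, all computed in a frame with the goal
plane at z = 0, x = 0 at the goal-mouth centre and y = 0 at the ground:

* **Required rate of closure** (RROC, m/s). General Tau theory writes
  interception as closing a gap x at rate ẋ in time τ = x/ẋ. Here the
  time available is fixed — the flight duration τ — so we solve for the
  *required* closure rate: RROC = gap / τ, with the gap measured from the
  reference point (0, 1) to the goal-line entry. The 1 m reference height
  reflects the midriff of a junior-skewed player population; the adult
  1.3 m variant used in earlier goalkeeping work is available through
  `goal_geometry(center = c(0, 1.3))`.
* **Spin-induced lateral deviation** ("curvature", m). Gravity acts only
  vertically, so absent spin the lateral motion is uniform and the ball
  would cross the line at `launch_x + vx * T`. The magnitude of the gap
  between that projection and the actual entry x measures how much the
  flight bent. The magnitude (not the signed value) enters the model:
  a keeper is wrong-footed by bend in either direction. The signed value
  is kept in the feature table (`curvature_signed`) for diagnostics.
  The recorded flight duration is used as the crossing time rather than
  re-deriving it from the z-velocity; the duration is authoritative
  metadata and the two are consistent by construction in clean data.
* **Shot angle** (degrees). The lateral angle of the shot origin from the
  goal-centre axis: `atan2(|launch_x|, launch_z)`, 0° from the penalty
  spot, 90° from the corner flag.

An OLS screen (`ols_screen()`) reports each feature's linear coefficient
and p-value against the goal proportion. It is a sanity check on whether
each feature carries signal, never a transformation of the data, and IQR
outlier flags (`iqr_outlier_flags()`, type-7 quartiles, 1.5 fences — the
conventional choice; the multiplier is an argument) likewise only report:
extreme flights are deliberately part of the difficulty range.

## The model and its parameterization

The score is a sigmoid of a linear index, bounded in (0, 1):

$$p \;=\; \frac{1}{1 + a\,b^{X}}, \qquad
  X = c\cdot RROC + d\cdot curvature + e\cdot angle .$$

The five constants are not jointly identifiable: replacing
$(c,d,e) \to k(c,d,e)$ and $b \to b^{1/k}$ leaves the curve unchanged.
We therefore fit the canonical logistic form

$$p = \mathrm{logit}^{-1}\!\big(\gamma_0 + \gamma_1 RROC +
      \gamma_2 curvature + \gamma_3 angle\big),$$

which has a unique optimum, and report classic constants with the
convention $b = e^{-1}$, $a = e^{-\gamma_0}$ (`legacy_constants()`); the
two forms agree to machine precision (this identity is tested).

**Loss.** Unweighted least squares on the proportions. Weighting by play
count is statistically tempting (binomial variance shrinks with plays) but
would let a handful of massively played routines dominate the curve; an
optional `weights` argument exposes it for sensitivity analysis, off by
default.

**Optimization.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
analytic Jacobian $-p(1-p)\,x$. Convergence: relative SSE change, step and
gradient tolerances all `1e-8`; iteration cap 10,000 at the interface
(the backend caps at 1024; fits here converge in well under 100).
Initialization is deterministic: $\gamma_0$ at the log-odds of the mean
target (clipped to [0.01, 0.99]), slopes at zero — inside the basin of
attraction whenever difficulty increases with the index, which the
monotone features guarantee in practice. Non-convergence returns the model
with `converged = FALSE` and a warning; `predict_all()` refuses such
models. A brute-force lattice evaluator (`grid_search_sse`, C++) exists
purely as an independent check that the LM solution is not a poor local
minimum.

**Numerical edges.** The sigmoid is evaluated through `plogis`
(overflow-safe); scores are clamped to the open interval at the
representable limits so downstream code can rely on $p \in (0,1)$.

## Validation machinery

* **Stratified 5-fold CV.** "Stratified" for a continuous target is
  implemented as quantile binning into `n_bins = 5` strata; each stratum
  is shuffled under the seed and dealt round-robin, with the deal
  continuing across strata so fold sizes stay balanced. Strata are formed
  with `findInterval` on the unique quantile values so that equal target
  values always share a stratum (a two-valued target stratifies exactly).
* **Standardized refit.** `fit_standardized()` scales features to mean 0,
  sd 1; predictions are unchanged (tested to 1e-6) but coefficient
  magnitudes become comparable, giving the feature-importance ranking
  (`coefficient_importance()`, ties broken in the fixed order rroc,
  curvature, shot_angle).
* **Goal-mouth grids.** `goal_mouth_grid()` bins entry points into a
  20 × 16 grid over the 7.32 m × 2.44 m mouth. Cells are half-open
  [low, high) with the final row/column closed, so posts and crossbar
  belong to edge cells; bin coordinates within 1e-9 of a cell boundary
  are snapped before flooring so the convention survives floating-point
  representation of the boundaries. Empty cells are `NA`, never 0 — a
  zone no shot entered is not a zone of certain saves — and entries
  outside the mouth are counted separately, not silently dropped.
* **Session scoring.** `session_score()` returns expected conceded
  (Σ scores), actual conceded, and the skill differential
  expected − actual, signed so that larger is better.
* **Baseline.** The pre-model linear "level of difficulty"
  (`baseline_difficulty()`) is winsorized above at 1 as is conventional
  for such scores, and additionally capped below at 0 — an extension
  adopted here for probability semantics.

## The synthetic generator

`generator_config()` + `generate_routines()` + `simulate_outcomes()`
produce data the pipeline can be tested against end to end, with a known
ground truth. The generator emulates:

* entry points across the full mouth as a mixture of a central cluster
  around the (0, 1) reference (sd 1.5 m × 0.6 m, truncated) and a
  corner-heavy tail (probability 0.4), because real shot sets are designed
  to span easy-to-unsaveable;
* flight durations uniform on 0.4–1.2 s (a 6–20 m strike at realistic
  ball speeds), launch distances 6–20 m, lateral launch positions with
  6 m spread;
* signed spin deviations N(0, 0.3 m);
* full physical consistency: vx is set so the spin-free projection lands
  at entry x minus the sampled deviation, vy satisfies the ballistic
  relation under g = 9.81 m/s², and vz closes the launch distance in
  exactly the flight duration (these identities are asserted in tests);
* outcomes as independent Bernoulli plays with p from the true sigmoid;
  an overdispersion knob mixes in beta-distributed per-play probabilities
  to emulate player heterogeneity. Routine generation and outcome
  simulation take separate seeds, so re-simulating outcomes never alters
  flights.

The default scenario is 600 routines × 200 plays with
γ = (−3, 0.9, 0.8, −0.02). Those weights were chosen once so that, under
the entry/duration ranges above, the standardized RROC weight is roughly
five times the curvature and angle weights — the hierarchy a post-shot
difficulty model should show, with placement-and-time dominating. The
fixed 200-play default is the parameter-recovery study condition; real
play logs are heavily long-tailed (a few routines played tens of
thousands of times), and `sample_plays_longtail()` provides that regime
(log-normal, clipped to [10, 50000]) where the split between fitted and
merely-scored routines matters.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: aerodynamic drag and Magnus forces (only the
lateral spin-free projection is modelled, matching the feature
definition), keeper biomechanics and positioning, correlation between
features induced by how shot designers program routines, non-stationary
player populations, and model misspecification itself — synthetic
outcomes come from the very sigmoid family being fitted, so recovery
tests certify the estimation machinery, not the adequacy of the
three-feature model for any particular app's data.

## Problem sizes and tolerances used in testing

The test suite works at deliberately modest scales chosen to make the
statistical assertions sharp: parameter recovery uses 20 replicate seeds
of 600 routines at 50/200/1000 plays (recovery tolerance
0.1·|γ| + 0.05, mean absolute error required to shrink monotonically in
plays); the optimizer check compares the LM fit against a dense 101⁴
lattice (±0.5, step 0.01) on a 50-routine instance; the physics check
integrates 100 flights at 1e-4 s steps against the closed form (1e-6 m
tolerance); the skill-cohort experiment uses six players with log-odds
offsets ±1.25, ±0.75, ±0.25 — a novice-to-semi-professional spread —
over 50 shots × 30 plays and 20 seeds. On the lattice check, note that
the SSE surface has a shallow ridge trading the intercept against the
slopes, so the best lattice point can differ from the continuous optimum
by more than one step in individual coordinates while agreeing in SSE to
a few 1e-5; the assertions therefore compare SSE values, not only
coordinates.

## Known limitations

* The model is a single global curve; it cannot express interactions
  (e.g. angle mattering more for slow shots) or player-specific ability,
  which is deliberate — folding ability into the score would mask the
  skill the metric exists to measure.
* Proportion targets hide how many plays back each routine; the default
  unweighted loss treats a 100-play proportion and a 50,000-play
  proportion as equally informative.
* Goal size is fixed; difficulty in apps with selectable goal sizes would
  need the geometry as a covariate.
* The spin-free projection is exact only if spin is the sole lateral
  force; strong wind or drag asymmetries would be absorbed into
  "curvature".
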