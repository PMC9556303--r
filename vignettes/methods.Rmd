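---
title: "Methods: data-driven human-in-the-loop exoskeleton optimization at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven human-in-the-loop exoskeleton optimization at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling choices behind `exoloop`: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the simulated participant does and does not emulate, and where the design
was genuinely open.

## The optimization stack

Assistance is a four-parameter torque pattern over the gait cycle: peak torque
(0–1 Nm kg⁻¹, mass-normalized; absolute torque is recovered at the reporting
layer by multiplying by body mass), peak time (40–55% gait cycle), rise time
(20–40%) and fall time (10–20%). Two cubic Hermite segments connect zero to
the peak and back, with zero slope at onset, peak and end. The torque pattern
itself is defined only by its four parameters; the Hermite family is the
smooth, monotone interpolant those parameters uniquely determine, and is the
convention of the emulator-controller lineage this parameterization comes
from. Fall time is capped at `toe_off − peak_time` so no torque is applied in
swing; when peak time sits near its 55% upper limit that cap falls below the
10% lower bound, in which case fall time clamps to 10% and the law carries a
non-fatal flag — peak times in that regime are exactly where fall time is
effectively pinned to its lower bound anyway. Toe-off defaults to 62% of the
gait cycle and is adjusted linearly with walking speed (−3% of the cycle per
m s⁻¹ around 1.25 m s⁻¹); the slope is a configurable placeholder for a
stance-duration model whose constants are not published with the protocol this
package follows.

Condition features are 30 within-bin means of ankle angle and of ankle
velocity over normalized phase (equal-width, half-open bins; within-bin mean
rather than center interpolation, so the feature is robust to sample count),
plus the four torque parameters in physical units, giving 64 values. Bins are
averaged across strides with equal stride weights — whether the original
pipeline weighted strides by duration is not recoverable, and equal weights
are the simpler declared choice. The first six strides after a law switch are
discarded as adaptation transient.

The preference classifier is a lasso-regularized logistic regression on
pairwise feature differences with no intercept, which enforces
`p_ij + p_ji = 1` identically. Both orders of every pair enter training, so
the dataset is antisymmetric. Two normalization choices deserve record:

* **Penalty normalization.** The regularization weight of 1 applies to the
  *summed* logistic log-loss (`glmnet` lambda = 1/N). Applied to the mean
  loss instead, the KKT condition at zero — |N⁻¹ Σ xᵢ(yᵢ − ½)| ≤ λ with
  z-scored features — is satisfied by the null model for any achievable
  correlation, so every weight would be exactly zero and the classifier could
  rank nothing. The summed-loss reading is also what the common scikit-learn
  parameterization (`C = 1`) implements.
* **Feature standardization.** Differences are z-scored per feature before
  the L1 fit and the weights mapped back to the raw scale; angle bins
  (degrees), velocity bins (degrees s⁻¹) and torque parameters (mixed units)
  make an unstandardized L1 penalty ill-posed.

Ties in training costs are dropped (a measure-zero event for continuous
costs); ranking ties break by law index with a stable sort.

The optimizer is standard CMA-ES with the usual constants: generation size
k = 4 + ⌊3 ln d⌋ (8 laws for d = 4, 6 for d = 2), log-decreasing
recombination weights over the top ⌊k/2⌋, cumulative step-size adaptation,
rank-one plus rank-μ covariance updates, initialized at σ = 0.1 (20% of each
normalized range) with identity covariance. Samples are clipped into the unit
box after sampling rather than resampled: evaluation noise dominates any
boundary bias at these problem sizes, and clipping keeps every update a convex
combination of feasible points so the mean stays in the box. The update is a
function of the candidate ranking only; any strictly monotone transformation
of the scores yields an identical update. Stopping is a fixed generation
budget (eight in the laboratory protocols).

## Speed adaptation and opportunistic optimization

Walking speed is estimated from stride period by ordinary least squares on a
short calibration walk — a linear model on the raw period, not its inverse,
fitted per participant; estimates are floored at zero. Control is causal with
a one-step lag: the speed of step t−1 selects the parameters of step t, with
the middle anchor as the declared fallback before any stride has been
observed. Between the per-speed anchors (0.75, 1.25, 1.75 m s⁻¹), each
parameter interpolates piecewise-linearly and clamps beyond the end anchors.

Real-world optimization accumulates 44 consecutive strides of one bout under
one law; a bout boundary before 44 clears the buffer and retries the same law,
so no evaluation ever mixes bouts or laws. Completed evaluations are credited
to the speed bin (boundaries 1.22 and 1.38 m s⁻¹; middle bin closed on both
edges) of their mean estimated speed — even if the candidate was drawn from a
different bin's queue, since what the classifier requires is that compared
evaluations share similar speeds, not a particular provenance. The per-bin
CMA-ES update therefore consumes the evaluated points explicitly. When a bin
completes a six-law generation, the other bins' means shift by
(σ_b / σ_init)·Δmean, clipped to the box: full coupling while a bin is still
uncertain, vanishing as it converges. Two consequences of that externally
injected mean change are handled deliberately: the receiving bin's evolution
paths are reset (they no longer describe its own sampling history), and the
opportunistic optimizer keeps each bin's σ non-increasing (`sigma_cap`),
treating σ as the remaining-uncertainty measure that the coupling rule reads —
the deployed behavior this mirrors is a convergence parameter that only
declines as evidence accumulates. The laboratory optimizer uses unmodified
step-size adaptation.

## Energetics

Breath power uses the Brockway coefficients (16.58 W per ml s⁻¹ O₂, 4.51 W
per ml s⁻¹ CO₂) — the conventional "standard equation" for indirect
calorimetry. Quiet standing (≥2 min) is subtracted from all walking
measurements. Steady-state cost averages the last 3 min of a 6-min condition
(closed-left windows: a breath at exactly 180 s is included); cumulative cost
integrates net power trapezoidally over the irregular breath times, through
3 min of recovery, because respiratory dynamics delay gas exchange relative to
muscular energy use and a first-order lag conserves the time integral. Cost
of transport is cumulative energy over distance; course speed is total
distance over total walking time, never a mean of bout speeds.

## The simulated participant

The simulator is the oracle for every test: optimizers see only its noisy
outputs while tests score against its stored ground truth.

* **Landscape.** Net metabolic rate is quadratic in normalized parameters,
  `base_rate(speed) + ½(x − x*)ᵀK(x − x*)`, the simplest landscape with a
  unique per-participant optimum and well-defined CMA-ES behavior. Curvature
  `K = diag(10, 16, 8, 4)` W kg⁻¹ per unit² is steepest in peak time — by far
  the strongest torque-parameter effect in practice — and shallowest in fall
  time, which is effectively pinned at its lower bound. With per-participant
  optima drawn at sd 0.1 around the generic parameters, the generic-to-optimum
  penalty is ~0.2 W kg⁻¹, the scale of generic-versus-optimized differences
  reported for this class of device. Optima shift with speed, and an outdoor
  context shifts them toward larger peak torque (+0.25 normalized), matching
  the observation that people accept more assistance overground.
* **Noise.** A 2-min steady-state metabolic estimate carries Gaussian noise
  of sd 0.10 W kg⁻¹ (an estimator-noise figure; between-participant
  variability is larger). Strides carry per-stride amplitude noise
  (sd 1.5°) and white sample noise (0.5°). These magnitudes were calibrated
  once so that generation-scale pairwise sign flips occur at a realistic
  10–20% rate — measured 13.6% for metabolic ranking and 17.9% for classifier
  ranking — and then frozen.
* **Kinematic response.** Two channels with distinct timing: a mechanical
  plantarflexion shift shaped like the torque profile itself (6° per
  Nm kg⁻¹), and a human-response shift peaking at toe-off (a cos² bump at
  62–66% phase) whose amplitude grows as the law's metabolic penalty shrinks
  (12° per W kg⁻¹). The separation matters: if both effects shared one shape,
  a linear classifier could separate benefit from torque magnitude only by a
  fragile cancellation against the parameter features, and on a symmetric
  quadratic landscape a purely parameter-linear response carries no pairwise
  label information at all. The response channel mirrors the empirical
  finding that benefit expresses as increased plantarflexion at toe-off —
  which is also the largest kinematic contributor the trained weights find.
* **Respirometry.** True power passes through a first-order filter (τ = 42 s,
  a literature-typical on-kinetics constant), is inverted to V̇O₂/V̇CO₂ at a
  fixed respiratory exchange ratio of 0.85, and sampled at ~4-s breath
  intervals with 3% multiplicative noise. The filter conserves energy, so
  cumulative-cost estimates are unbiased given ≥5τ of recovery.
* **Schedules.** Naturalistic sessions draw bout lengths from a log-normal
  with median 40 steps (90% under 100) and bout speeds from a mixture placing
  one-third of bouts in each speed bin, with 5–10 s standing rests; the
  sinusoidal treadmill varies 0.75–1.75 m s⁻¹ with a 30-s period.

What the simulator does **not** emulate: human learning beyond the fixed
six-stride transient, within-bout speed drift and terrain, non-quadratic or
drifting metabolic landscapes, correlated (non-Gaussian) respirometry noise,
sensor dropout, and any musculoskeletal detail. Passing tests therefore show
that the pipeline is correct and that the method behaves as intended under a
realistic noise budget — not that these effect sizes transfer to humans.

## Problem sizes and numerical choices

The default simulated prior dataset is 5 training participants × 160
conditions (≈127,000 training pairs) — about a quarter of the ~3,600
conditions behind the original classifier, chosen so the full train-and-
optimize cycle completes in about a minute; residual weights on uninformative
bins at this scale slightly degrade rankings relative to the large-data
regime. Method-equivalence experiments use 9 simulated participants with two
eight-generation protocols each; real-world experiments use one-hour sessions
across 20 seeds. Covariance eigenvalues are floored at 1e−20 before square
roots; normalization round-trips are exact to 1e−12; every source of
randomness flows through a single seed per experiment, and checkpoints store
doubles at 15 significant digits so resumed sessions continue bit-for-bit.

## Known limitations

Both optimization routes reach their evaluation-noise floors ~0.08–0.09
normalized units from the true optimum after eight generations, so the
distance *between* their two answers sits near 5% of the parameter range — the
method-equivalence margin is intrinsically tight at these noise levels rather
than comfortably met. The classifier transfers across simulated participants
because the response channel is cost-referenced; real between-subject
transfer is harder. The cross-bin proportionality constant (σ_b/σ_init) and
the stance-fraction slope are declared choices where no published constant
exists, and are worth a sensitivity analysis before any hardware use.
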