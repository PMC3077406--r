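---
title: "Methods: Bayesian slant estimation from active optic flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian slant estimation from active optic flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slantflow)
```

## The problem

A planar surface slanted by `σ` about the horizontal axis (tilt fixed at
90°), viewed by an observer translating laterally at velocity `v` while
fixating the surface at distance `d`, rotates in egocentric coordinates at
`ω = v/d` rad/s. To first order, the image velocity of a feature at angular
elevation `β` within a small patch around fixation is

```
v(β) = ω · (1 + β · tan σ),
```

so the flow's only slant-bearing component is its gradient with respect to
elevation, the deformation

```
def = ω · tan σ.
```

The linearization is used within a patch of ±4° (±0.07 rad) around
fixation; `local_velocity()` rejects larger elevations. The exact pinhole
projection lives in `project_dots()` and serves as the generative oracle for
this approximation: differencing two projected frames and regressing
horizontal angular velocity on elevation recovers def (the test suite checks
agreement to within 5% inside the patch).

Given one measured `def`, slant is not identifiable: every pair on the
hyperbola `tan σ · ω = def` is consistent with the image data. The package
implements two Bayesian observers that resolve the ambiguity differently,
and the simulation and analysis machinery to contrast them.

## The two estimators

Both observers share:

* a **flatness prior** on the slant tangent `Σ`: half-Gaussian centered at 0
  with spread `σ_Σ` (surfaces tend toward frontoparallel);
* a **rigidity likelihood**: the measured def is Gaussian around
  `Σ · Ω` with spread `σ_def`;
* a grid posterior over `(Σ, Ω)`, marginalized over `Ω` by trapezoidal
  quadrature and read out at the **posterior median**, the Bayes estimator
  under absolute-error loss. We verify numerically (rather than assume) that
  for the retinal model the median agrees with the closed-form
  center-of-mass prediction.

They differ in the prior over the relative rotation magnitude `Ω`:

* **Inverse-optics**: a *stationarity* prior — the surface is believed
  stationary, so `Ω` is Gaussian around the egocentric rotation `ω_E`
  measured from the head's translation, with spread `σ_Ω` expressing the
  precision of that extra-retinal signal (truncated at 0 and renormalized).
  As `σ_Ω, σ_def → 0` the posterior concentrates at the true slant; as
  `σ_Ω` grows the median decreases monotonically (slant under-estimation),
  and the estimate no longer depends on velocity and slant through def
  alone.
* **Retinal-only**: no head-motion information. We implement the
  noninformative prior as a *zero-centered half-Gaussian* with spread
  `σ_Ω`. Under this choice the posterior median follows
  `k·√def` with `k = √(σ_Σ/σ_Ω)` — the defining signature of the
  retinal account. We considered a bounded-uniform rotation prior instead;
  numerically its posterior median does not scale as `√def` times a
  spread-ratio constant (the ratio drifts by several percent across the def
  range and is governed by the grid bound rather than a prior spread), so it
  cannot express the `k·√def` law this model exists to formalize. The
  bounded-uniform kind remains available (`rotation_prior("uniform")`) as a
  sensitivity variant.

The two accounts coincide when head-motion information is absent: an
inverse-optics observer with a very broad rotation prior reproduces the
retinal median (tested at spread 20 rad/s to within 1%).

## Numerical implementation

The posterior is evaluated on a base grid of 512 × 512 nodes covering
`Σ ∈ [0, 10]` (tan 80° ≈ 5.67 lies well inside) and
`Ω ∈ [0, ω_max]`, with `ω_max = max(1, ω_E + 5σ_Ω)` for the stationarity
prior, `max(1, 5σ_Ω)` for the half-Gaussian, and the upper bound for the
uniform. A configuration whose grid would hold less than 99% of either
prior's mass is rejected up front.

Two refinements keep median readouts accurate when the posterior is much
narrower than a base grid cell (tight priors or a tight likelihood):

* *anchor nodes*: for the stationarity prior, extra nodes are always placed
  around `ω_E` and around `def/ω_E`, so a near-degenerate posterior cannot
  fall between coarse nodes;
* *adaptive refinement*: after a first pass, each axis's mass window
  (cells carrying all but 1e-9 of the mass, padded by 3 cells) receives a
  dense cluster of nodes and the density is re-evaluated once. Trapezoidal
  weights handle the resulting non-uniform axes exactly.

The median is read from the interpolated cumulative trapezoid; it is stable
under doubling the grid to within 1% (tested). Degenerate inputs error
explicitly: an all-zero marginal, an unnormalized marginal (integral off by
more than 1e-3), or a likelihood too tight for any node to catch mass.

`σ_def` defaults to a coefficient-of-variation parameterization
(`σ_def = 0.05 · def`, floored at 1e-4 rad/s so the likelihood stays proper
at `def = 0`); an absolute mode is available. The measurement spreads used
for the published figures are not recoverable from the source material, so
they are free parameters here; defaults were chosen once as plausible
values and the qualitative contrasts do not depend on them.

## What the synthetic generator emulates

`make_trajectory()` idealizes the back-and-forth lateral head translation as
a sinusoid `x(t) = A sin(2πt/T)` with `A = 25` mm (peak-to-peak 50 mm, the
experiment's maximum lateral shift) and period set by the required peak
velocity (`T = 2πA/v_peak`), truncated after 11 half-cycles. At the fast
peak velocity (285.6 mm/s) this lasts 3.02 s, consistent with the stated
fast-regime duration; the slow regime (57.7 mm/s) then implies about 15 s,
which does not match the stated 11.1 s — the stated durations, peak
velocities and shift cannot be jointly reconciled under a single periodic
trajectory, so durations are not used as constraints. The human average-speed
feedback bands (83 ± 40 mm/s normal, 20 ± 10 mm/s slow) are likewise
inconsistent with a sinusoid at the stated peaks; `velocity_band_check()`
implements the bands but is advisory only.

A *def cycle* is the interval between consecutive velocity zero-crossings
(one sign-constant lobe of def); leading and trailing partial lobes are
dropped, and the per-trial `max_def` is the mean over complete cycles of the
per-cycle peak of |def|. For the sinusoid this equals `(v_peak/d)·tan σ` and
is insensitive to sampling rate above the enforced minimum of 20 samples per
half-cycle (±0.1%, tested).

`generate_trials()` reproduces the block designs — AVV/PVV: 5 repetitions ×
slants {20, 35, 50, 65, 80}° at 860 mm; AVP: 4 repetitions × {10, 20, 40,
50}° at 760 mm — with subjects assigned between-subjects to the velocity
regimes (34 subjects by default, alternating assignment). The PVV block can
replay the AVV def values (`replay_from`), mirroring the passive replay of
the active stimuli. Responses are `k·√def` plus Gaussian noise (SD 0.218 on
the tangent scale), floored at 0 since judgments are magnitudes in
[0°, 90°]; no ceiling is applied on the tangent scale. Default condition
slopes are the fitted behavioral values (PVV 1.04, AVV 1.88, AVP 2.41).

What the generator does *not* emulate: human kinematic variability (the
trajectory is deterministic, so def is constant within a regime × slant
cell), per-subject differences in `k` (subjects are exchangeable by
default), texture/foreshortening cues of the physical surface, the irregular
aperture mask, and photometric detail of the displays. Passing tests
therefore show that the pipeline recovers its own generating structure at
the experiment's design sizes — not that real observers behave this way.

## Analysis choices

The original inference used linear mixed-effects models with MCMC intervals.
Here the scientific contrasts are preserved with self-contained tools:

* `no_intercept_slope()` — least-squares slope of the response on `√def`
  through the origin (`Σxy/Σx²`), the behavioral summary statistic.
* `agreement_statistic()` — a Vonesh-style model concordance:
  `1 − Σ(y−ŷ)² / (Σ(y−ȳ)² + Σ(ŷ−ȳ̂)² + n(ȳ−ȳ̂)²)`. It is 1 only at exact
  agreement, 0 when the model does no better than the observed mean, can be
  negative, and is invariant to a common shift of both vectors (all
  unit-tested). The exact algebraic variant used originally is not
  recoverable from the source material; this implementation follows the
  cited concordance definition.
* `velocity_effect_test()` — asks whether velocity regime affects responses
  beyond its effect on def. The design confounds regime with the def range
  (slow subjects only ever see small defs), which makes a naive
  label-permutation test anti-conservative: the true labeling is maximally
  collinear with the `√def` regressors, so the observed coefficient has a
  larger sampling variance than relabeled ones. We therefore use a
  Freedman–Lane scheme — permute reduced-model residuals in subject-sized
  blocks, rebuild pseudo-responses, re-estimate the regime contrast — with
  per-condition `√def` slopes and a ±1/2 regime contrast. The test's size
  at nominal 0.05 is checked by simulation in the suite. Because def ranges
  never overlap between regimes, a planted additive regime offset is partly
  absorbed by the slope terms; the test detects it, but the coefficient
  under-states it. This is a property of the design, not of the test.
* `collapse_diagnostic()` — per-velocity `√def` slopes of a simulation
  table and their spread, with an optional group-label permutation p-value:
  near zero for the retinal model, strictly positive for inverse-optics
  with non-negligible `σ_Ω`.
* `observed_vs_predicted()` — OLS of responses on `k_condition·√def`
  with confidence bounds and the agreement statistic.

## Problem sizes and determinism

The shipped tests and the acceptance script run the estimators on 512² base
grids (about 0.05 s per posterior after refinement), the Monte Carlo
contrast on the 5 slants × 2 velocities design, slope recovery on 100
simulated datasets of 17 subjects per condition, and the permutation-size
check on 300 reduced-size datasets — a few minutes in total. Every random
draw flows from an explicit integer seed; simulation tables, trial tables
and all emitted CSVs are bit-identical across reruns with the same seed, and
each CSV carries a header with the package version, seed, and a hash of the
generating configuration.

## Known limitations

* The retinal model's `k·√def` law is exact only in the small-noise limit;
  with `σ_def` above ~10% of def, or prior spreads far from unit order, the
  grid median departs from the closed form by more than the tested 3%.
* Estimates below ~2 base grid cells (tan σ ≲ 0.04) are resolution-limited
  when priors are broad; the adaptive refinement targets concentrated
  posteriors, not heavy-tailed ones.
* Tilt is fixed at 90° throughout; second-order flow (accelerations) and
  texture cues are out of scope by design.
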