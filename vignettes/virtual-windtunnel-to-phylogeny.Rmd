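---
title: "From virtual wind-tunnel records to characters on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From virtual wind-tunnel records to characters on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerophylo)
```

## The measurement model

aerophylo analyses the static aerodynamics of gliding and maneuvering animal
bodies the way a six-axis force-balance experiment does. A model of the
animal is held in a wind tunnel on a rear sting at a commanded orientation
(roll $\phi$, pitch $\theta$ = angle of attack $\alpha$, yaw $\psi$), the
sensor records force and torque in its own frame, and the data reduction
chain recovers dimensionless moment coefficients:

1. **Frame transformation.** Sensor-frame vectors are rotated into the
   tunnel-aligned frame by $R = R_z(\psi)\,R_y(\theta)\,R_x(\phi)$ (the
   standard aerospace intrinsic z-y'-x'' sequence, applied to column
   vectors), and torques are translated from the sensor mount to the center
   of mass: $M_{com} = R\,M_s + (R\,r)\times(R\,F_s)$, with $r$ the
   COM-to-sensor offset. The composition order is a convention the source
   experiments leave open; it is fixed and documented here, and the
   synthetic generator uses the same convention, so the round trip is exact.
2. **Nondimensionalization.** Each moment becomes a coefficient through
   $M = \tfrac12 \rho U^2 C \lambda S$, with $\lambda$ the snout-vent length
   and $S$ the planform area. $\lambda$ also serves as the reference length
   of the Reynolds number $Re = U\lambda/\nu$; at the default
   $U = 6\,\mathrm{m\,s^{-1}}$, $\lambda = 8\,\mathrm{cm}$ and
   $\nu = 1.5\times10^{-5}\,\mathrm{m^2\,s^{-1}}$ (air at roughly 20 °C),
   $Re = 32{,}000$. Coefficients are treated as Re-independent across the
   bluff-body range explored (30,000-70,000), and the generator is
   quasi-static by construction, so this invariance is exact in simulation.
3. **Derivatives.** Static stability about each axis is the sign of
   $\partial C/\partial(\text{angle})$ near an operating point: a negative
   slope restores perturbations. Control effectiveness is
   $\partial C/\partial\delta$, the coefficient change per radian of
   appendage deflection. Both are estimated at a low (15°) and a high (75°)
   angle of attack, stability additionally for pitch at 0° and at the
   pitching equilibrium ($C_m = 0$ trim point), eight stability and twelve
   control quantities in all.

## Slope estimation and its confidence intervals

Stability slopes are ordinary least squares of coefficient on angle (in
radians) over all replicate-level points within a window of ±10° around the
evaluation point — three grid steps at the 5° measurement increment, inside
which the archetype curves are designed to be exactly linear. The
experiments this emulates report a 75% confidence level for coding but not
the estimator; we use the two-sided Student-t interval on the OLS slope,
with a bootstrap deliberately left out to keep the estimator auditable.
Control effectiveness uses a central difference
$(C_{+\delta}-C_{-\delta})/2\delta$ where both deflection signs were
tested (symmetric protraction, tail dorsiflexion, pronation/supination)
and a one-sided difference against the undeflected baseline for one-sided
movements (wing tuck, tail lateral flexion), averaged over the window;
its interval comes from replicate scatter (recordings within one sweep
share a zero-offset state and are not independent, so differences are
first averaged within replicate pairs).

Equilibria are located as sign changes of the replicate-mean pitching
moment between adjacent grid angles, refined by linear interpolation. When
several crossings exist, the character uses the lowest-$\alpha$ crossing
with a locally negative slope if there is one, else the lowest crossing —
the trim point an animal would actually sit at; all crossings are still
reported. A series that never changes sign yields a missing ("?")
equilibrium character.

## Discretization and mapping

Stability codes as *stable*, *marginal*, or *unstable* by whether the 75%
interval lies below, across, or above zero. Control codes as *effective*
when $|\partial C/\partial\delta| > 0.09\,\mathrm{rad^{-1}}$ (strict), the
moment-coefficient derivative needed to overcome the measured stability of
a weathervane — equivalently to displace the center of pressure by about
10% of body length; the absolute value is used because sign encodes
direction, not capability. The resulting taxa × 20 matrix (symbols 0/1/2
for stability, 0/1 for control, `?` missing) is written as a
Mesquite-compatible NEXUS STANDARD block; a continuous matrix of raw slopes
is exported alongside but not used by parsimony.

Ancestral states are reconstructed per character by unordered parsimony,
implemented as Sankoff dynamic programming with unit cost between distinct
states — equivalent to Fitch counting on binary trees and well defined on
hard multifurcations, which consensus phylogenies contain. Missing tips
contribute zero cost to every state. A second pass computes, for every
node, the full MPR set (states attainable under at least one
most-parsimonious assignment); no ACCTRAN/DELTRAN resolution is imposed.
Branch lengths are ignored throughout, and the score is invariant to root
placement.

## What the synthetic wind tunnel emulates

Physical experiments cannot ship inside a package, so every stage is
exercised by a generator that inverts the reduction chain. Ground truth for
a taxon is a set of analytic coefficient curves: the pitch curve is a
piecewise cubic Hermite interpolant through (angle, value, slope) knots, so
target slopes at 0°, 15°, 75° and the equilibrium crossing are exact by
construction, not fitted; roll and yaw respond linearly to body angle per
angle-of-attack regime; control enters additively as
$\delta\cdot\partial C/\partial\delta$, matching the linearized
effectiveness definition. Records are produced by dimensionalizing the
truth coefficients, expressing them at the sensor
($M_s = M_{com} - r\times F$), rotating by the inverse Euler matrix, and
adding noise.

The noise model has two parts, both Gaussian in the sensor frame:

* **Per-sample noise**, 0.02 N and $2\times10^{-3}$ N·m SD, averaged over
  600 samples per one-minute-style recording. The recorded mean is drawn
  directly with SD $\sigma/\sqrt{600}$ — distributionally identical to
  averaging the samples, and 600× cheaper.
* **Residual zero offsets**: the sensor is re-zeroed (tunnel stopped)
  before each recording block, and the offset left after zeroing
  ($1.25\times10^{-4}$ N, $2.5\times10^{-4}$ N·m SD) is constant within a
  block and independent between blocks. Long pitch sweeps are zeroed
  block-wise (boundaries at 27.5°, 57.5°, 87.5°) so each fitting window
  lies inside one block; shorter roll/yaw and deflection sweeps form single
  blocks. Within a window such an offset is orthogonal to the angle
  regressor: it inflates residual scatter and hence the reported intervals
  without biasing slopes. This is the deliberate, physically motivated
  reason pipeline confidence intervals *over*-cover at zero — a body with
  truly zero slope codes marginal far more often than the nominal 75% —
  while the interval remains exactly calibrated on plain i.i.d. noise,
  which is how the coverage property is tested.

The SDs were fixed by a signal-to-noise design calculation: the coded-state
separations (±0.5 rad⁻¹ stability truths; 0.30 vs 0.03 rad⁻¹ control
truths against the 0.09 threshold) sit more than five standard errors from
their decision boundaries at the default design (5° grids, 5 replicates),
so recovery failures are dominated by genuinely marginal cases.

What the generator does **not** emulate: unsteady and flapping
aerodynamics, added-mass or damping terms, Reynolds-number dependence,
aeroelastic wing deformation, sting interference beyond the zero-offset
model, and any net aerodynamic force model (lift/drag are out of scope, so
true forces are zero plus noise). Passing tests therefore demonstrate that
the *reduction and inference chain* is correct and calibrated, not that
real measurements would be this clean.

### A degenerate input worth knowing about

For a body whose moment curve is identically zero (the sphere calibration
object), the pitching equilibrium is ill-posed: any crossing the estimator
finds is selected by noise, and with block-wise zeroing those crossings
concentrate at block boundaries, where the offset step between blocks
enters the local slope fit. In repeated simulations the seven fixed-angle
stability characters each code marginal in well over 90% of runs, but the
equilibrium character does so only about half the time, so the joint event
"all eight characters marginal" is substantially rarer than the product of
the others. This is a property of the discretization rule applied to a
zero-signal input, not an estimator defect; the corresponding strict check
in the acceptance suite documents it by failing.

## Defaults and problem sizes

| Parameter | Default | Meaning |
|---|---|---|
| `pitch_grid` | 0-90° by 5° | angle-of-attack sweep |
| `body_grid` | -20-20° by 5° | roll/yaw sweeps at each regime |
| `aoa_regimes` | 15°, 75° | low/high evaluation angles |
| `replicates` | 5 | recordings per position |
| `window` | ±10° | slope-fitting half-width |
| `ci_level` | 0.75 | two-sided confidence level |
| `threshold` | 0.09 rad⁻¹ | control-effectiveness cutoff |
| `U`, `rho`, `nu` | 6, 1.204, 1.5e-5 | tunnel speed, air density, viscosity |
| `snout_vent`, `planform_area` | 0.08 m, 0.02 m² | reference geometry |

Movement extents follow the tested repertoire: symmetric wing protraction
±45°, tail dorsiflexion ±15°, asymmetric pronation/supination 15°, tail
lateral flexion 30° and single-wing tuck 45° (one-sided). The test-design
enumeration is fully explicit in `design_points()` rather than replaying
any historical position count, since published per-series totals do not
reconcile exactly.

Verification sizes were chosen to keep the whole suite within a few
minutes on one CPU: 1000 random trees of up to 7 tips against exhaustive
enumeration for parsimony, 10,000 simulated series for interval
calibration, 1000 random rotations for frame invariants, 200 random taxa
for end-to-end character recovery, and 20-40 seeded runs per calibration
fixture.

## A small worked run

```{r demo, eval = FALSE}
cfg <- run_config(seed = 1)
res <- run_pipeline(cfg, "demo_run")
res$matrix                 # 8 taxa x 20 characters
res$reconstructions$stab_pitch_eq$score
head(res$report)
```

## Known limitations

* The per-axis assignment of movements to the twelve control characters
  (tail dorsiflexion and symmetric protraction to pitch; wing tuck and
  asymmetric pronation/supination to roll; tail lateral flexion and
  asymmetric pronation/supination to yaw) follows the axes those movements
  predominantly excite; cross-axis effectiveness is not modeled.
* Equilibrium characters inherit the ill-posedness described above whenever
  the true curve is flat near zero.
* Only uniform (unordered) state-change costs are supported; no step
  matrices, no likelihood or Bayesian reconstruction, no tree inference —
  trees are inputs.
* The continuous character matrix is exported for downstream use but no
  continuous-trait comparative methods are provided.
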