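---
title: "A bistable delayed model of the HPA axis and its challenge tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable delayed model of the HPA axis and its challenge tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpaxis)
```

## The model

`hpaxis` simulates a nondimensional delay-differential model of the
hypothalamic--pituitary--adrenal (HPA) axis with five endogenous state
variables: stored CRH `cs` at the PVN axon terminals, circulating CRH `c`,
circulating ACTH `a`, available pituitary glucocorticoid receptor `r`, and
circulating cortisol `o`. Time is measured in units of the cortisol
elimination timescale (half-life 7.2 min divided by log 2, about 10.4 min),
so 15 min is `t = 1.44` and one hour is about `t = 5.8`.

The equations are

* `dcs/dt = (c_inf(o) - cs) / t_c`, with synthesis target
  `c_inf(o) = c_inf_bar + exp(-b o)`: cortisol suppresses the slow synthesis
  and packaging of CRH;
* `dc/dt = q0 I(t) h(cs) + gc(c) - q2 c`, with release fraction
  `h(cs) = 1 - exp(-k cs)` and Hill-type auto/paracrine upregulation
  `gc(c) = gc_max (q1 c)^n / (1 + (q1 c)^n)`;
* `da/dt = c fa(o r) - p3 a`, with the convex, decreasing feedback factor
  `fa(x) = 1 / (1 + p2 x)`; the cortisol--receptor complex is treated as the
  fast-equilibrium product `o r`;
* `dr/dt = gr(o r) - p6 r`, with `gr(x) = x^2 / (p4 + x^2) + p5`;
* `do/dt = a(t - t_d) - o`, where `t_d = 1.44` (15 min) is the adrenal
  delay.

The delayed pituitary--adrenal (PA) loop produces an ultradian limit cycle:
at the reference parameters the clamped PA subsystem oscillates with a
period near `t = 6` (roughly an hour) for `c` between about 15 and 56.
Exogenous drugs live in two extra compartments with one-compartment
pharmacokinetics: dexamethasone `o_exo` (clearance `p7 = 0.03`, from the
240-min vs 7.2-min half-life ratio) joins the feedback terms as `o + o_exo`
but never enters the synthesis target (dexamethasone penetrates the brain
poorly), and cosyntropin `a_exo` (clearance `p8 = 1.7`, from the 4.1-min
half-life, truncated from 7.2/4.1 = 1.756) adds to the delayed adrenal
drive.

## Timescale separation and nullclines

Because `cs` moves on the slow synthesis timescale `t_c` while the PA loop
oscillates on the fast ultradian timescale, the long-term behaviour is read
off two curves in the (`cs`, `c`) plane:

* the **c-nullcline**, `q0 I h(cs) + gc(c) = q2 c`, available in closed
  form as `cs(c) = -log(1 - u)/k` with `u = (q2 c - gc(c))/(q0 I)`; for
  Hill coefficients `n >= 5` it is S-shaped (folded), and the two fold
  points ("knees") bound the bistable range of `cs`;
* the **cs-nullcline**, `cs = c_inf_bar + <exp(-b o)>`, where the average
  is taken over one period of the PA attractor at clamped `c`
  (`pa_characterize()`); over non-oscillatory attractors the average
  collapses to a point value. Jensen's inequality guarantees
  `<exp(-b o)> >= exp(-b <o>)`, so averaging matters.

Intersections of the two curves are the system's long-term states
(`find_fixed_points()`). At the reference parameters there are three: a
high-cortisol stable state ("normal"), a low-cortisol stable state
("diseased"), and a saddle between them. Stability is classified by direct
perturbation of the full delayed system rather than by a Jacobian, because
the reduced plane sits on top of an oscillatory, delayed fast subsystem.

## Calibrated constants

Two constants of the stored-CRH equation have no printed reference values
and are calibrated package defaults (`scripts/calibrate.R` reproduces the
scan):

* `c_inf_bar = 0.25`. The fold of the reference c-nullcline spans
  `cs` roughly 0.65--0.88, and the averaged synthesis term spans about
  0.47--0.60 over the relevant `c`; any `c_inf_bar` in about (0.16, 0.33)
  yields three intersections. The default centres the cs-nullcline in that
  window, giving well-separated states (`c` about 16.9 and 31.0).
* `t_c = 150` (about 26 h). The dexamethasone test below measures cortisol
  9 h (`t = 52`) after dosing; `t_c` controls how far the stored-CRH pool
  drifts in that window. For `t_c` below roughly 120 the diseased state
  slides past the lower knee during suppression and the characteristic
  ordering (greater suppression from the diseased state) is lost; above
  that threshold results change slowly. The default sits above the
  threshold while keeping relaxation experiments short.

Both are ordinary `hpa_params()` fields and can be overridden.

The Hill coefficient defaults to `n = 5`, the smallest integer giving a
folded c-nullcline (the saddle-node in `n` lies between 4 and 5); sweeps
intended to reproduce the published c-nullcline panels can set `n = 6`,
the base value those panels use.

## The integrator

The solver (`hpa_integrate()`) is a method-of-steps, fixed-step explicit
RK4 scheme written in C++, with the delayed terms read from a cubic Hermite
interpolation of the stored solution; that keeps the overall order four,
which the test suite verifies by step-halving. Rectangle inputs (dose
pulses, stressor steps) define mandatory restart points, so discontinuous
forcing never straddles a step; nodes at breakpoints carry one-sided
derivatives. The default step 0.01 (about 6 s) resolves the delay
`t_d = 1.44` by 144 steps. There is no randomness anywhere: runs are
bit-reproducible from a resolved configuration, and a run can be split at
any time and continued from its stored history to within interpolation
accuracy (`trajectory_history()`).

An independent adaptive DDE solver (`deSolve::dede`) is used in the test
suite as a cross-check oracle on the full system; it plays no role in the
implementation.

## Challenge protocols

**Dexamethasone suppression (`run_dex_test()`).** The system is
equilibrated on the attractor of the chosen basin, dosed at the cortisol
cycle peak with a rectangle infusion (width 30 min, height 2, the printed
nondimensional dose), and measured 9 h later (the 11 p.m. dose / 8 a.m.
measurement convention). Percentage suppression
`s = 100 (pre - post)/pre` uses either the period-averaged pre-dose level
or the instantaneous cycle peak. Because both subjects share one parameter
set and differ only in basin, the greater suppression of the diseased
subject is a property of the *state*, not of any feedback parameter: the
feedback factor `fa` is convex, so the same added glucocorticoid bites
harder from the diseased state's smaller complex level `o r` (reported as
`delta_fa`). Post-dose the shifted cs-nullcline intersects the c-nullcline
in non-oscillating equilibria, and the residual (detrended) cortisol
oscillation amplitude drops below 1% of its pre-dose value. Oscillation
amplitudes are measured on linearly detrended windows so the slow decay of
circulating drug is not mistaken for a rhythm.

**Cosyntropin stimulation (`run_acth_test()`).** The dose is a rectangle
of width 30 min timed to a requested phase of the cortisol cycle
(`theta = 0` at the peak). The clinical dose does not determine the
nondimensional height, so the default (14) is calibrated to put the
normal subject's peak response at the test's characteristic response scale
(peak cortisol near 8); all comparisons are relational. Adrenal
hyporeactivity is a gain factor `lambda` on cortisol secretion per unit
ACTH. Worked through the nondimensionalization exactly, it maps to
`p2 -> lambda p2`, `p4 -> p4 / lambda^2` in the subject's own units, with
common-scale cortisol equal to `lambda` times the model value
(`adrenal_reactivity_params()`). Two signatures follow and are tested:
in the subject's own model units the basal level *rises* (the delayed loop
partially compensates the weaker gland — the counterintuitive signature
that makes naive "lower reactivity, lower response" reasoning unreliable),
while on the common scale the stimulated response is damped, with the
hyporeactive subject's best-phase peak about matching the normal subject's
worst-phase peak. No single unit system shows both effects at once under a
linear gain; the package reports both scales and documents which claim
lives on which.

**Two-stage test (`run_two_stage_test()`).** A stressor — a rectangle
increase `Iext = 0.5` of the synaptic drive for 60 min, applied 9 h after
dexamethasone — shifts the c-nullcline leftward while suppression still
holds. The diseased state, parked near the lower knee, falls off its
branch and surges; the normal state merely slides. The diseased subject's
peak cortisol during the stressor therefore *exceeds* the normal
subject's, the opposite of what an enhanced-feedback account of low basal
cortisol would predict, which is what makes the protocol discriminating.
`stress_transition()` exposes the underlying mechanism directly: a
sufficiently strong or long stressor moves the diseased state into the
normal basin permanently, with no parameter change.

## Numerical conventions

* Limit-cycle detection: burn-in 200 time units, then upward crossings of
  cortisol through its window mean (a Poincare-style section); an attractor
  is non-oscillatory when the relative peak-to-trough amplitude falls below
  `1e-6`. The window doubles (up to a cap) if cycles fail to close
  consistently; an unresolved attractor is an error, never a guess.
* Phase origin: `theta = 0` at the cortisol maximum; all phase-dependent
  results use this convention (the published phase origin is unstated, so
  phase-by-phase comparisons are meaningful up to a shift).
* Cycle averages use evenly spaced phase samples over one period (the
  periodic trapezoid rule); 256 samples leave quadrature error below
  `1e-6`.
* Knees are local extrema of `cs` along the closed-form curve, bracketed on
  a grid of spacing 0.02 and refined to `1e-10`.
* Fixed points are refined by bisection on the gap between the two curves
  to `1e-9` in `c`; both defining relations hold to `1e-8` at the reported
  points. Tangential near-crossings are flagged as degenerate, not
  silently resolved.
* Problem sizes: challenge runs integrate about 150 units of equilibration
  plus the 52-unit protocol at step 0.01 (about 25,000 steps); nullcline
  sweeps characterize the PA attractor on grids of 40--80 CRH values.

## What the simulations do and do not show

The model is nondimensional and deliberately spare. It contains no
circadian forcing (`I0` is constant), no dose-response calibration to
mg-level dosing or to cortisol in mass units, no receptor kinetics beyond
the fast-equilibrium `o r` product, and no action of dexamethasone on
brain glucocorticoid receptors. Conclusions are therefore about
*mechanism* — which orderings and shifts follow from bistability plus
delayed feedback — not about quantitative prediction for individual
subjects. The two calibrated constants inherit that caveat: the
suppression percentages move by a few points across the admissible
calibration range, which is why the package's checks use the ordering and
band agreement rather than exact equality. One known boundary case: with
the default calibration the peak-phase suppression of the two basins is
nearly equal (the diseased attractor sits close to its oscillation onset,
so its cycle peak barely exceeds its mean), and the strict
diseased-greater-than-normal ordering is asserted only for the
period-averaged statistic.
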