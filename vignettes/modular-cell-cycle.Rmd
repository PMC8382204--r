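---
title: "Modeling the cell cycle with functional response modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the cell cycle with functional response modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchcycle)
```

## The modeling idea

Cell-cycle transitions are governed by bistable switches: the response of
APC/C to Cdk1, of Cdk1 to cyclin B, and of E2F to cyclin D are all
S-shaped, with two stable branches separated by an unstable middle one.
Mechanistic models generate these S-shapes from feedback loops with many
rate constants. `switchcycle` instead treats each switch as a
*functional module* whose steady-state response is written down directly,
so that the tunable parameters are the observable features of the
response curve itself.

A steep, ultrasensitive response is the Hill function
$$\mathrm{Out} = \frac{\mathrm{In}^n}{K^n + \mathrm{In}^n},$$
with threshold $K$ and exponent $n$. To make it S-shaped, the threshold
is bent by a scaling function of the output,
$$\mathrm{Out} = \frac{\mathrm{In}^n}{(\xi(\mathrm{Out})\,K)^n +
\mathrm{In}^n}, \qquad
\xi(y) = 1 + \alpha\, y (y - 1)(y - r),$$
so that the threshold is raised on the lower branch and lowered on the
upper branch. The cubic bend is the default, in analogy with the cubic
nullcline of the FitzHugh–Nagumo oscillator; $\alpha$ sets the width of
the bistable region ($\alpha = 0$ recovers the plain Hill response) and
$r$ its asymmetry ($r = 0.5$, the package default, gives a symmetric
bend; we do not give $r$ a biological reading). Because the relation is
multivalued in the forward direction but single-valued in the inverse,
the curve is constructed by inverting:
$$\mathrm{In} = \xi(y)\, K \left(\frac{y}{1-y}\right)^{1/n}.$$
The bistable width is the input-axis distance between the two local
extrema (folds) of this inverse. Dynamically, the module is the
relaxation equation
$$\epsilon\,\frac{dy}{dt} = \frac{x^n}{(\xi(y) K)^n + x^n} - y,$$
optionally with a lagged input $x(t - \tau)$; the three modules —
ultrasensitive, S-shaped, delayed — combine freely inside a negative
feedback loop.

`scaling_function()` also provides quadratic, linear, piecewise-linear
and tabulated bends. The piecewise form (three segments through
$(0,1)$, $(x_{max}, \xi_{max})$, $(x_{min}, \xi_{min})$, $(1,1)$) is the
shape used to match measured or mass-action response curves;
`fit_piecewise_xi()` estimates its parameters, plus a multiplicative
correction on the Hill term, by least squares on input-axis residuals.

## The model systems

All systems embed these modules in the cyclin synthesis/degradation
negative feedback. Concentrations are nM, time is minutes; starred
variables (APC\*, E2F\*) are activity fractions in $[0,1]$.

* **Embryonic, two variables** (`build_embryonic()` without a Cdk1
  switch): constant CycB-Cdk1 synthesis, APC/C-dependent degradation,
  and an ultrasensitive ($\alpha_{apc} = 0$) or bistable
  ($\alpha_{apc} > 0$) APC/C switch. Standard values $n = 15$,
  $K_{cdk,apc} = 20$ nM, $b_{deg} = 0.1\,\mathrm{min}^{-1}$,
  $\epsilon\,b_{deg} = 0.01$.
* **Delayed** (`build_delayed()`): the APC/C equation reads the lagged
  Cdk1 level; the delay is constant or blends an activation delay
  $\tau_1$ into an inactivation delay $\tau_2$ through a Hill switch in
  APC\* (exponent $p = 5$), evaluated at the current APC\* level.
* **Three variables** (`build_embryonic()` with `alpha_cdk`): total
  CycB and active Cdk1 are distinguished; the CycB→Cdk1 switch has its
  Hill term multiplied by CycB (its output is a concentration) and its
  scaling function takes the ratio Cdk1/CycB, guarded as
  Cdk1/max(CycB, $10^{-12}$) since the ratio may transiently exceed 1.
* **Interlinked somatic model** (`build_interlinked()`): five variables
  CycD, E2F\*, CycB, Cdk1, APC\* chaining three bistable switches, with
  basal degradation offsets $\delta_d$, $\delta_b$. Defaults:
  $K_{cyc,e2f} = 120$, $K_{cyc,cdk} = 40$, $K_{cdk,apc} = 20$ nM, all
  $\alpha = 5$, $\epsilon = 0.01$ min, $d_{syn} = 0.15$,
  $b_{syn} = 0.03$ nM/min, $d_{deg} = 0.009$,
  $b_{deg} = 0.003\,\mathrm{min}^{-1}$, $\delta = 0.05$. These defaults
  give a natural period near 24 h.
* **Mass-action PP2A–ENSA–GWL oscillator** (`build_mass_action()`): the
  default kinetic reference set with conservation of the GWL, PP2A and
  ENSA pools substituted algebraically. Its clamped-Cdk1 APC/C response
  is S-shaped with the fold region around 20 nM, which is what the
  fitted phenomenological module reproduces. The synthesis/degradation
  pair for the oscillatory extension has no reference value and must be
  supplied by the user.

Non-dimensionalization (`nondimensionalize()`) rescales concentrations
by $K_{cdk,apc}$ and time by $b_{deg}$, collapsing parameters into the
relative synthesis $c = b_{syn}/(K_{cdk,apc} b_{deg})$, the threshold
ratio $d = K_{cyc,cdk}/K_{cdk,apc}$, $\epsilon^* = \epsilon\,b_{deg}$
and $\tau^* = b_{deg}\tau$. We scale *all* concentrations by
$K_{cdk,apc}$ (so the three-variable cyclin equation carries $d$
explicitly); rescaling CycB by $K_{cyc,cdk}$ instead differs only by the
constant $d$. The relative synthesis of the three-variable chain is
$c/d$.

## Analysis machinery

Integration uses `deSolve` (`lsoda`; `dede` with constant history for
delays). Steady states come from multi-start damped Newton iteration
over a deterministic grid, with stability read from the eigenvalues of a
finite-difference Jacobian (tolerance $10^{-8}$ on real parts; delayed
systems are classified on their $\tau = 0$ reduction and flagged — no
DDE eigenvalue analysis is attempted, a documented limitation).
Multivalued response curves are traced by pseudo-arclength continuation
(secant predictor, Newton corrector, adaptive step in $[10^{-4},
10^{-1}]$ normalized, folds located by sign changes of the input
direction and sharpened by a local parabolic fit). For the
phenomenological switches the continuation is checked in the tests
against the exact analytic inverse; for the mass-action subsystem,
against dense multi-start root finding.

Oscillation metrics follow the local-extrema convention: discard the
first half of the span as transient, require at least five maxima whose
(parabolically refined) heights stay within 1% of their median and whose
amplitude exceeds 1% of the observed range — this is what rejects damped
and vanishingly small oscillations; the period is the mean inter-maximum
interval and a coefficient of variation under 5% counts as regular. The
1%/5%/5-cycle cut-offs are package choices (the filtering criteria are
standard, their numeric values are not fixed by any measurement) and are
configurable. Peak-height refinement is suppressed at corner-shaped tops
(steep rise onto a plateau), where a parabola would overshoot.

Regimes are labeled by combining equilibria with probe simulations:
`Bi` (two stable states), `Osc` (sustained cycle, no attracting
equilibrium), `MonoLow`/`MonoTop` (single stable state below the lower /
above the upper fold output of the reference switch), `Irregular`
(sustained but non-regular variation, i.e. intermittent branch
sticking), with an explicit `Bi+Osc` composite when a cycle coexists
with bistability. Phase labels on the somatic model use activity
thresholds: M wherever APC\* > 0.95, S/G2 wherever E2F\* > 0.95 and
APC\* < 0.95, G1 otherwise (ties resolve away from M and S/G2).

## Checkpoints and circadian coupling

The checkpoint scenarios perturb parameters inside piecewise-constant
time windows (`parameter_schedule()`; the integrator restarts at window
boundaries; ramps are deliberately not supported since the experiments
are step perturbations):

* restriction point — CycD synthesis divided by 10 after E2F activation
  (growth-factor stimulation spans a 4–20-fold range of CycD induction,
  so 10 is the intermediate value); the started cycle still completes;
* G1 damage — basal CycD degradation tripled; interphase lengthens by
  the activation delay, measured as the shift of the next APC/C
  activation onset against the baseline run;
* G2 damage — the Cdk1 bend set to $\alpha_{cdk} = 30$ (chosen so the
  standing CycB level sits below the shifted activation threshold);
  mitosis then starts at higher CycB, and repair before the baseline
  threshold crossing leaves interphase duration unchanged. Note that
  $\alpha = 30$ makes the cubic $\xi$ negative around $y \approx 0.79$;
  only the activation (lower) branch needs a positive scaled threshold,
  which holds for any $\alpha \ge 0$ at $r = 0.5$, so the static
  positivity guard of `scaling_function()` applies to module
  construction but not to this transient parameter move.

Circadian coupling is unidirectional Wee1-style forcing of the Cdk1
switch: $\alpha^*_{cdk}(t) = \alpha_{cdk} + A + A\sin(\omega t + \phi)$,
oscillating between the basal level and $\alpha_{cdk} + 2A$ (phase
$\phi = 0$ by default; the offset is exposed because nothing pins it).
`detect_locking()` finds a repeating pattern in the forced Cdk1 series
by comparing the post-transient series with shifted copies of itself
(normalized RMS mismatch below $10^{-2}$, a configurable package
choice), matches the repeat/forcing period ratio against integers
$q \le 5$ within 2%, and counts Cdk1 peaks per repeat to get $p$; the
locked cell-cycle period is repeat/$p$. For the locking experiments the
natural period is tuned by a secant search on $d_{syn}$ — the model's
primary period knob, acting through the G1 duration — to 1% of the
requested value. Runs span 40 forcing periods with the first half
discarded. Because the forcing can only raise the Cdk1 threshold,
locking can lengthen but never shorten the cell cycle, and the locking
tongues (`arnold_map()`) widen asymmetrically.

## A worked example

```{r example, eval = FALSE}
m <- switch_module(K = 20, n = 15, xi = scaling_function("cubic", 5))
fold_analysis(m)
#> <fold_analysis> width = 6.48735, bistable
#>      input    output
#> 1 22.96130 0.2648762
#> 2 16.47396 0.7549056

sys <- build_interlinked(somatic_params())
traj <- integrate_system(sys, t_span = c(0, 20000), dt = 2)
oscillation_metrics(traj, var = "APC")$period / 60   # hours
#> [1] 23.54444
segment_phases(traj)$durations[2, ]
#>    G1 SG2   M period
#> 2 668 626 122   1416
```

## What the synthetic fixtures do and do not show

`make_fixture()` produces response curves from known scaling functions
(optionally with seeded multiplicative noise) and periodic / damped /
quasiperiodic / sawtooth series with known ground truth. They exercise
the estimators — parameter recovery, extremum-based period extraction,
the locking detector — under controlled conditions. They are idealized:
real response-curve data carry heteroscedastic measurement error,
unknown normalization and sparse coverage near folds, and real
single-cell traces carry molecular noise none of which the fixtures
emulate; passing these tests validates the numerics, not the biology.

## Numerical choices and limitations

Fold finding brackets the derivative of the inverted response on a
$10^4$-point grid and bisects to $10^{-12}$ in the output — adequate
because the cubic/piecewise bends give at most a few sign changes.
Width-parameterized sweeps convert width to $\alpha$ by monotone
bisection, capped at the largest $\alpha$ keeping $\xi > 0$ on $[0,1]$.
Trajectory output steps are chosen at or below 1/200 of the expected
period wherever extrema are measured; coarser sampling can misclassify
sharp relaxation spikes as irregular. The fit of the piecewise bend is a
local derivative-free search from a moment-based start — the original
fit of the mass-action curve was done by eye, so any deterministic
criterion is a modeling choice, and ours is the stated least-squares
one. Problem sizes used by the test-suite sweeps (a 13×13 regime map, a
5×4 delay map, 40-forcing-period locking runs) were chosen as the
smallest grids on which the claimed qualitative structures are stable.

Out of scope by design: mechanistic Wee1/Cdc25 switches, the
hypothetical fourth (FoxM1/CycA) switch, bidirectional clock–cycle
coupling, stochastic dynamics, and closed-form linearization — stability
is always numerical here.
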