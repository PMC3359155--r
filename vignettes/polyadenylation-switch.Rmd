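---
title: "A bistable translational switch: model, reductions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable translational switch: model, reductions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpebswitch)
```

## The biological loop

During synaptic plasticity, the abundant kinase αCaMKII can promote its
own synthesis: its active, phosphorylated form (X~P~) phosphorylates the
translational regulator CPEB1 (Y), and phospho-CPEB1 (Y~P~) drives
cytoplasmic polyadenylation of αCaMKII mRNA, recruiting the translation
machinery (T) to produce new inactive kinase (X).  Synthesis competes
with first-order degradation of the free kinase.  Because the feedback
is strongly nonlinear — activation requires the autocatalytic
X + X~P~ → 2X~P~ step — the loop can hold two stable total-kinase
concentrations: a basal "down" state and an elevated "up" state, with an
unstable separatrix between them.  `cpebswitch` implements this loop at
four nested levels of description and the analyses that connect them.

## Model levels

**Full model (6 ODEs).**  Mass-action kinetics over six reactions:
Ca~4~CaM activation X ⇌ X~P~ (k10/k1010), the autophosphorylation
complex X·X~P~ = C1 (k1/k2) with catalysis C1 → 2X~P~ (k3),
dephosphorylation of X~P~ by a phosphatase P (k4), CPEB1 activation via
the complex Y·X~P~ = C2 (k5/k55, catalysis k6), dephosphorylation of
Y~P~ (k7), and synthesis via the translation complex Y~P~·T = C3
(k8/k88, catalysis k9 releasing one new X).  Free X and X~P~ relax
toward small basal levels at rates λ2, λ1; complexes do not degrade.
Free CPEB1 is carried by exact conservation Y = Y~T~ − Y~P~ − C2 − C3,
so six ODEs close the system (`full_rhs()`).

**3-ODE reduction.**  Setting the fast complex derivatives to zero
(pseudo-steady state, as in the Michaelis–Menten derivation) and
approximating Y = Y~T~ − Y~P~ leaves (X~T~, X~P~, Y~P~) with
dX~T~/dt = k9·C3 − λ·X~T~ (`reduced3_rhs()`).  This is exact for the
steady states of the complexes but assumes, crucially, that *total*
kinase degrades at rate λ — true only when little kinase is
complex-bound.

**1-ODE model.**  On the X~P~ and Y~P~ nullclines the pool balance
becomes dX~T~/dt = G′(X~T~) − λ·X~T~ with the saturating synthesis
function G′(X~T~) = c·h(X~T~)/(h(X~T~) + P7/a), where h inverts the
exact steady-state map X~T~ = f(X~P~) (`xt_of_xp()`).  The map cannot be
inverted in closed form, so h is a degree-9 polynomial least-squares fit
with zero intercept (`fit_inversion()`).

**Steady-state quartic.**  Clearing denominators of the full steady-state
balance gives a quartic in X~P~ with zero constant term
(`steady_state_polynomial()`): X~P~ = 0 is always a steady state and the
others are polynomial roots — fixed points without any integration.
Two notes on this polynomial.  First, the exact elimination actually
factors as X~P~ times a quadratic times the shared factor (a·X~P~ + P7);
retaining that factor keeps the conventional degree-4 form at the cost
of one spurious, always-negative root that the nonnegativity filter
removes.  Second, the published closed-form coefficients contain an
undefined symbol; `printed_z_diagnostic()` evaluates them under every
plausible reading and reports the mismatch, but all computation uses the
re-derived coefficients.

## Parameters and the calibration

Rate constants are the published table values (with the unit
corrections noted in the documentation of `loop_params()`); condition I
uses k3 = 500 s⁻¹ (fast catalysis, negligible trapping) and condition II
k3 = 0.5 s⁻¹ (substantial kinase bound in C1).  Four concentrations are
not published: P, T, Y~T~ and resting Ca~4~CaM.  The package freezes
them once, as follows (`calibrate_free_concentrations()`):

* **Two fitted scalars.**  The reduced steady states depend on the free
  concentrations almost exclusively through the synthesis capacity
  c = k9·k8·T·Y~T~/(k88 + k9) and the dephosphorylation rates P7 = k7·P,
  P4 = k4·P.  T and P are therefore fitted — deterministically, by
  nested 1-D solves — so the quartic's stable and unstable roots match
  the two published baseline values (95 and 9.4 μM at λ = 10⁻⁴ s⁻¹,
  condition I).  Every other reported value is out-of-sample for this
  calibration.
* **A structural floor.**  The unstable fixed point sits at the
  autophosphorylation onset X ≈ (P4 + k1010)·(k2 + k3)/(k1·k3) ≈ 9.41 μM
  plus a term increasing with P, so the fit runs to the lower end of the
  physiological phosphatase window ([0.01, 100] μM) and accepts a +0.6%
  residual on the unstable root; the upper root is matched exactly.
* **Y~T~ = 50 μM, chosen once.**  At the up state the translation
  machinery holds C3 ≈ λ·X~T~/k9 ≈ 0.12 μM of CPEB1.  The reduced
  levels neglect this sequestration (Y = Y~T~ − Y~P~), so their
  agreement with the full model in condition I — a central qualitative
  claim — requires Y~T~ ≫ 0.12 μM.  50 μM, commensurate with the ~95 μM
  kinase pool, keeps the correction at the 0.5% level.  Only the product
  T·Y~T~ enters c, so this choice trades off against T (≈ 0.30 μM after
  calibration) with almost no downstream effect.
* **U_basal = 10⁻⁶ μM** (resting Ca~4~CaM effectively zero, so the down
  state sits at the basal kinase level) and **U_stim = 10 μM** (a
  saturating physiological Ca~4~CaM transient).

The frozen configuration ships as
`inst/extdata/frozen_config.json`; because the calibration is seed-free
it can be regenerated bit-identically (`frozen_config(recompute = TRUE)`).

## The stimulus protocol, honestly

The narrative experiment applies a 10-second Ca~4~CaM pulse to drive the
loop from down to up.  Under *any* configuration that reproduces the
published fixed points, that cannot work from the basal state: the total
kinase pool at rest is 10⁻⁴ μM while the separatrix is near 9.4 μM, pool
growth is capped by the synthesis ceiling c ≈ 9.5 × 10⁻³ μM s⁻¹ (≥ ~17
minutes to reach the separatrix even at full throttle), phospho-CPEB1
charging is capped by a·Y~T~·X~P~, and X~P~ itself collapses within
~1/k1010 ≈ 1 s of pulse offset.  Direct integration confirms that no
pulse amplitude switches the system (`switching_threshold(...,
vary = "U_stim")` reports no-switch).

The package therefore makes the up-state protocol explicit: up runs
start from a *primed* state carrying a bolus of phosphorylated kinase
equal to twice the separatrix (`up_state_init()`, margin configurable),
with the 10-s pulse applied on top.  The bolus stands for the outcome of
an induction event — sustained local translation or kinase influx —
that this model does not resolve.  The priming threshold itself is a
meaningful readout: it tracks the separatrix and rises as CPEB1
activation (k5) weakens.

## Numerical choices

* **Integration**: `deSolve::lsoda`, rtol 10⁻⁸, atol 10⁻¹² μM — the
  states span 10⁻⁴ to ~3.6 × 10² μM.  Square pulses are handled by
  segmenting the integration at the pulse edges, never by smoothing.
* **Steady-state horizons**: up-state runs integrate to 60/λ.  In
  condition II, kinase trapped in complexes escapes degradation, which
  stretches the slowest pool timescale by the factor
  X~T~/(X + X~P~) ≈ 3.8; 10/λ is visibly unconverged there.
* **Root finding**: quartic roots via `polyroot` (imaginary-part
  tolerance 10⁻⁹ relative; roots above −10⁻¹² snapped to zero);
  reduced3/full fixed points via damped Newton with numerical Jacobians,
  seeded from the quartic roots mapped through the pseudo-steady-state
  composition, accepted only when |RHS| < 10⁻⁹ μM/s.  Stability: leading
  Jacobian eigenvalue (|eig| < 10⁻¹⁰ s⁻¹ labelled marginal).
* **Inversion fit**: 500 X~P~ grid points (half geometric from 10⁻⁹ μM,
  half linear) up to the X~P~ giving X~T~ = 1.5× the upper fixed point;
  unweighted least squares on a basis scaled by the domain width.  The
  map has a sharp corner at the autophosphorylation onset (width set by
  k10·U_basal ≈ 10⁻⁹): below it the true X~P~ is ~10⁻⁸ μM, which no
  global degree-9 polynomial can follow.  Consequently the 1-ODE level
  reproduces the upper and basal states tightly but carries a ~6% low
  bias at the unstable point, and round-trip accuracy is asserted only
  on the upper branch.  h is clamped at zero inside G′.
* **Continuation**: warm-started root tracking on dense grids (linear
  for λ over the published range [2 × 10⁻⁵, 10⁻³]; log for k5 over
  [10⁻⁵, 10⁻¹]), branch matching by |ΔX~T~|/(1 + X~T~) < 0.25,
  saddle-nodes refined by bisection to 10⁻³ relative.  Branch
  comparisons use a 0.5 μM absolute floor so the basal branch is not
  compared relatively against zero.

## What the synthetic conditions do and do not emulate

The generator reproduces the study conditions exactly: the two k3
regimes, the 10-s square pulse, and log-uniform perturbed-parameter
ensembles for robustness scans.  It does not emulate features of real
synapses that the model itself omits: stochasticity of small copy
numbers, calcium dynamics upstream of Ca~4~CaM, multi-subunit CaMKII
holoenzyme structure, or mRNA availability.  Passing tests therefore
certify the mathematical claims about this reaction scheme — level
agreement, bistable ranges, hysteresis — not quantitative predictions
for tissue.

## Known limitations

* The k5-shifted fixed points are genuine out-of-sample predictions and
  land within ~8% (stable) and ~13% (unstable) of the published values;
  the two published numbers for that shift are not jointly reachable
  for any phosphatase level once the baseline pair is imposed, so part
  of this gap is inherited from the source rather than the fit.
* The λ value at which bistability is lost (~7 × 10⁻⁴ s⁻¹ here) depends
  on the same unpublished phosphatase level and is reported, not tuned.
* Hysteresis in λ is one-sided over the published range: the up-state
  branch collapses at the saddle-node, but the basal state never jumps
  up because it remains stable throughout — the switch is reversible
  only by re-priming, not by lowering degradation.

## A worked mini-example

```{r example, eval = FALSE}
cfg <- frozen_config()
p <- make_condition("I", cfg)
solve_fixed_points(p, "quartic")      # three states: ~0, ~9.4, 95 uM
compare_levels(p)$max_discrepancy     # < 0.15 across all levels
tr <- integrate_loop(p, state0 = up_state_init(p, "full"),
                     protocol = make_stimulus(10, cfg$U_stim),
                     t_end = 6e5, level = "full")
tail(tr$XT, 1)                        # relaxes onto the upper state
```

The numbered scripts under `analysis/` run the complete study —
calibration, reduction and fit, level comparison, switching dynamics,
and bifurcation/robustness — writing tables under `results/`, and
`scripts/acceptance.R` recomputes the headline values from scratch.
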