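# cpebswitch

Bistable switching in the CPEB1–αCaMKII cytoplasmic-polyadenylation
feedback loop.

## The problem

Long-lasting synaptic changes need protein levels that stay elevated for
far longer than any single molecule survives.  One proposed mechanism is
a translational positive feedback: active, phosphorylated αCaMKII
(X<sub>P</sub>) phosphorylates the cytoplasmic polyadenylation element
binding protein CPEB1 (Y → Y<sub>P</sub>), and Y<sub>P</sub>, bound to
the translation machinery (T), drives polyadenylation of αCaMKII mRNA
and synthesis of new kinase (X), against first-order degradation of the
free kinase at rate λ.  `cpebswitch` is for modellers who want to ask
whether — and over what parameter ranges — this loop is a bistable
switch, and how far the standard model-reduction toolbox can be trusted
on it.

## The model and its reductions

Mass-action kinetics over six reactions give a 6-ODE model in
(X, X<sub>P</sub>, Y<sub>P</sub>, C1, C2, C3), where C1 = X·X<sub>P</sub>
(autophosphorylation complex, catalysis k3), C2 = Y·X<sub>P</sub>
(CPEB1 activation) and C3 = Y<sub>P</sub>·T (translation).  Free CPEB1
follows by exact conservation.  The package implements, and compares,
four nested levels:

1. **full** — the 6-ODE mass-action system;
2. **reduced3** — pseudo-steady-state elimination of C1–C3, leaving
   (X<sub>T</sub>, X<sub>P</sub>, Y<sub>P</sub>) with the pool balance
   dX<sub>T</sub>/dt = k9·C3 − λ·X<sub>T</sub>;
3. **one_d** — a single ODE dX<sub>T</sub>/dt = G′(X<sub>T</sub>) −
   λ·X<sub>T</sub>, with the saturating synthesis function
   G′(X<sub>T</sub>) = c·h(X<sub>T</sub>)/(h(X<sub>T</sub>) + P7/a)
   built on a degree-9 zero-intercept polynomial inversion
   X<sub>P</sub> = h(X<sub>T</sub>) of the exact steady-state map;
4. **quartic** — a steady-state polynomial in X<sub>P</sub> (zero
   constant term, so X<sub>P</sub> = 0 is always a root) whose
   nonnegative real roots are the fixed points with no integration at
   all.

On top sit fixed-point location and Jacobian stability analysis at every
level, stimulus-driven switching experiments, warm-started bifurcation
sweeps over λ and the CPEB1-activation rate k5 with saddle-node
refinement, and a deterministic calibration that freezes the free
concentrations the rate table does not provide (see the vignette in
`vignettes/` for the full account).

## Worked example

```r
library(cpebswitch)

cfg <- frozen_config()             # calibrated reference configuration
p   <- make_condition("I", cfg)    # fast autophosphorylation, k3 = 500/s

solve_fixed_points(p, "quartic")
#>   model_level        XT          XP        YP stability leading_eigenvalue
#> 1     quartic  0.000000  0.00000000  0.000000    stable      -9.999996e-05
#> 2     quartic  9.455293  0.03995212  4.955374  unstable       2.086034e-02
#> 3     quartic 95.000000 85.30620779 49.788042    stable      -9.952942e-05
```

Three steady states: the basal "down" state, the separatrix near
9.4 μM, and the up-regulated state at 95 μM total kinase.  A primed
trajectory (a phospho-kinase bolus clearing the separatrix with a 2×
margin, plus the 10-s Ca₄CaM pulse) relaxes onto the upper state of the
full model:

```r
tr <- integrate_loop(p, state0 = up_state_init(p, "full"),
                     protocol = make_stimulus(10, cfg$U_stim),
                     t_end = 6e5, level = "full")
tail(tr$XT, 1)
#> [1] 95.0428
```

and the switch is robust in the CPEB1-activation rate:

```r
dk <- sweep_bifurcation(p, "k5", 10^seq(-5, -1, length.out = 200))
bistable_range(dk)
#> $lo 6.08e-05   $hi 0.1   $decades 3.22
```

With condition II (`make_condition("II", cfg)`, k3 = 0.5/s) the same up
run ends near 360 μM at the full level but near 95 μM at every reduced
level: kinase trapped in complexes escapes degradation, and the pool
balance the reductions rest on breaks — the loop's central cautionary
result.

## The analysis workflow

The numbered scripts reproduce the complete study, writing tables under
`results/`:

```sh
Rscript analysis/01_calibrate.R     # freeze P, T, YT against the baseline states
Rscript analysis/02_reduction.R     # steady map, inversion fit, printed-form check
Rscript analysis/03_fixed_points.R  # all levels x both conditions + parameter shifts
Rscript analysis/04_dynamics.R      # up/down trajectories, switching thresholds
Rscript analysis/05_bifurcation.R   # lambda and k5 diagrams, saddle nodes, robustness
```

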