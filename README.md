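# hkbdyn

Bifurcation and coordination-regime analysis of the Haken–Kelso–Bunz (HKB)
model of joint action, in the full four-dimensional state space.

## The model

The HKB model couples two hybrid Rayleigh–Van der Pol oscillators, each
describing the end-effector position `x_i(t)` of one agent in a rhythmic
coordination task:

```
x1'' + x1' (alpha x1^2 + beta x1'^2 - gamma) + omega1^2 x1 = I12
x2'' + x2' (alpha x2^2 + beta x2'^2 - gamma) + omega2^2 x2 = I21
I12 = (a + b (x1 - x2)^2) (x1' - x2')  =  -I21
```

`alpha` and `beta` weight the Van der Pol and Rayleigh damping
nonlinearities, `gamma` is the linear anti-damping (oscillations exist for
`gamma > 0`), `omega_i` are the eigenfrequencies (rad/s) and `a`, `b` are
the coupling strengths.  Most of the literature reduces this system to a
single equation for the relative phase under a slowly-varying-amplitude
approximation; this package instead analyses the full first-order system
in `(x1, x2, y1, y2)` for general coupling strengths, where in-phase
(relative phase 0°), anti-phase (180°) and genuinely phase-locked
(intermediate, constant phase) periodic solutions live, together with
their symmetry-breaking bifurcations, period-doubling cascades, chaotic
regimes, bistability and hysteresis.

It is aimed at researchers in coordination dynamics and movement
neuroscience who need quantitative stability boundaries of coordination
regimes — for instance when parametrising a virtual partner driven by an
HKB oscillator.

What the package provides:

* **Single-oscillator analysis** — closed-form classification of the
  trivial state, Hopf criticality via the first Lyapunov coefficient
  `l1 = -(alpha + 3 beta omega^2) / (2 omega (omega^2 + 1))`, and the
  behaviour at infinity on the Poincaré sphere: equilibria on the equator,
  their types, and the critical damping `gamma*` at which the limit cycle
  is destroyed in a heteroclinic transition (`estimate_gamma_star()`).
* **Numerical continuation** — pseudo-arclength continuation of
  equilibria and periodic orbits by orthogonal collocation (NTST = 50,
  NCOL = 4, Newton tolerance 1e-9), Floquet multipliers from the
  collocation monodromy, detection and bisection localisation of folds
  (SN), symmetry-breaking branch points (BP), period doublings (PD) and
  Hopf points, branch switching, two-parameter fold loci and the
  fold–Hopf organising centre (`continue_periodic_branch()`,
  `coupled_mode_branch()`, `switch_branch()`, `find_fold_hopf()`).
* **Regime analysis** — fast compiled time stepping, relative phase from
  per-oscillator peak times, regime classification, attractor enumeration
  and a Benettin largest-Lyapunov-exponent estimator.
* **Experiments** — uncertainty quantification of phase-lag distributions,
  quasi-static hysteresis sweeps, frequency-ratio (heterogeneity) studies
  and bistability scans, driven by a registry of named study scenarios
  (`get_scenario()`, `list_scenarios()`).

## Worked example

Criticality of the single-oscillator Hopf bifurcation and the heteroclinic
destruction of its limit cycle:

```r
library(hkbdyn)

hopf_criticality_single(osc_params(alpha = 1, beta = 1, gamma = 0, omega = 2))
#> Hopf bifurcation at gamma = 0: supercritical (l1 = -0.65)

estimate_gamma_star(alpha = -1, beta = 1, omega = 2)
#> gamma* = 3.65860619  (bracket [3.65860608, 3.65860629], period at lower end 8.921)
#>   period law T = 4.364 + 0.281 * -log(gamma* - gamma), R^2 = 0.98871
```

The branch of stable oscillations born at `gamma = 0` grows with `gamma`;
its period follows `T = A - B log(gamma* - gamma)` and diverges at
`gamma* ≈ 3.6586`, where the cycle collides with four saddle equilibria at
infinity and disappears — beyond that damping the model has no bounded
oscillation at all.

Bistability of coordination regimes (anti-phase and phase-locked) in the
coupled model, and the fold that produces hysteretic transitions:

```r
p <- coupled_params(alpha = -1.7, beta = 0.5, gamma = 1.7, omega = 2.3,
                    a = 0.5, b = -0.5)
enumerate_attractors(p, random_initial_conditions(12, seed = 42, scale = 1))
#> 2 distinct attractor(s):
#>   phase-locked basin  8  lag +-84.9 deg  T 3.433
#>   anti-phase   basin  4  lag +-180.0 deg  T 2.745
```

Two attractors coexist: an anti-phase solution and a pair of phase-locked
solutions at relative phase ±85° with unequal amplitudes.  Continuing the
phase-locked orbit in `omega` locates the saddle-node at `omega ≈ 2.39`
where it is destroyed; a quasi-static sweep of `omega` up and back down
(`quasi_static_sweep("fig11_hysteresis", ...)`) jumps from ~90° to 180°
near the fold on the way up and never jumps back — hysteresis.

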