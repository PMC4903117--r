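---
title: "Coordination dynamics of the HKB model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordination dynamics of the HKB model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical methods, the tunable
parameters and the design decisions behind `hkbdyn`.  It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model and its invariant structure

A single HKB unit is the planar hybrid Rayleigh–Van der Pol oscillator

$$\dot x = y,\qquad
  \dot y = -y\,(\alpha x^2 + \beta y^2 - \gamma) - \omega^2 x .$$

Two units are coupled through
$I_{12} = (a + b\,(x_1-x_2)^2)(y_1-y_2) = -I_{21}$, giving a
four-dimensional first-order system in $(x_1, x_2, y_1, y_2)$ (this state
ordering is used everywhere).  All parameters are dimensionless except the
eigenfrequencies $\omega_i$ (rad/s).  The heterogeneous variant replaces
$\omega^2 x_i$ by $\omega_i^2 x_i$ and nothing else.

Two exact reductions organise the computations for identical oscillators:

* the **in-phase manifold** $x_2 = x_1,\ y_2 = y_1$ is invariant and the
  coupling vanishes on it, so in-phase orbits are single-oscillator limit
  cycles;
* the **anti-phase manifold** $x_2 = -x_1,\ y_2 = -y_1$ is invariant and
  the restricted dynamics is again a single HKB oscillator with
  $\alpha_{\rm eff} = \alpha - 8b$ and $\gamma_{\rm eff} = \gamma + 2a$.

`coupled_mode_branch()` continues these families in the reduced planar
system (cheap and well conditioned) while stability and symmetry breaking
are judged from the Floquet multipliers of the **full** 4D system along
the embedded orbit.  Two corollaries of the reduction are used as test
oracles: the anti-phase Hopf locus of the trivial state is
$\gamma = -2a$ (independent of $b$, matching the factorisation of the
origin's characteristic polynomial into
$\lambda^2-\gamma\lambda+\omega^2$ and
$\lambda^2-(\gamma+2a)\lambda+\omega^2$ in sum/difference coordinates);
and the fold–Hopf organising centre in the $(\gamma, b)$ plane sits at the
degenerate-Hopf (Bautin) point of the reduced oscillator,
$b = (\alpha + 3\beta\omega^2)/8$, which is $13/8 = 1.625$ for
$\alpha=\beta=1$, $\omega=2$.  `find_fold_hopf()` does **not** use this
closed form: it locates SN$_\mathrm{A}$ by one-parameter continuation for
a sequence of $b$ values and bisects until the fold meets the Hopf line,
as an honest numerical computation; the closed form only cross-checks it.

A consequence worth knowing: the transverse linearisation of an in-phase
orbit coincides with its tangent linearisation when $a = 0$ (the
$b$-coupling is quadratically small on the diagonal), so in-phase orbits
are transversally **marginal at $a = 0$ and unstable for every $a > 0$**,
for any $b$.  This fixes the in-phase stability boundary at $a=0$ exactly
and is why, in the uncertainty-quantification study below, no mass can
accumulate at $0^\circ$ when $a$ is sampled from a strictly positive
interval.

## Linear stability and Hopf criticality

The origin's Jacobian is $[[0,1],[-\omega^2,\gamma]]$; the classification
in `classify_trivial_single()` follows the discriminant
$\gamma^2 - 4\omega^2$, with the boundary cases $\gamma = 0$ and
$|\gamma| = 2\omega$ reported as `non-hyperbolic` rather than folded into
neighbouring classes.  Hopf criticality uses the first Lyapunov
coefficient in closed form,
$l_1 = -(\alpha + 3\beta\omega^2)\,/\,(2\omega(\omega^2+1))$, with
transversality $\partial\mathrm{Re}\,\lambda/\partial\gamma = 1/2$;
$\alpha + 3\beta\omega^2 = 0$ is the degenerate case and is refused as a
branch start.

## Behaviour at infinity

`sphere_project()` maps the plane onto the upper unit hemisphere
($X = x/\sqrt{1+x^2+y^2}$, …); the equator represents infinity.  The
pushforward vector field carries a $1/Z^2$ singularity at the equator;
multiplying by $Z^2$ (a positive time rescaling) yields a polynomial
field, which is what `compactified_rhs(..., desingularized = TRUE)` and
all equator computations use.  Equilibria at infinity solve
$X Q_3 - Y P_3 = -XY(\alpha X^2 + \beta Y^2) = 0$ on the unit circle:
always $(\pm 1, 0)$ and $(0, \pm 1)$, plus four diagonal points with
$\alpha X^2 + \beta Y^2 = 0$ exactly when $\alpha\beta < 0$ (eight in
total).  We work from this derived condition rather than from a printed
closed form for the diagonal points, because direct substitution shows
the latter has the $X$ and $Y$ expressions interchanged; for
$|\alpha| = |\beta|$ the two readings coincide.

Only $(0, \pm 1)$ are hyperbolic (stable nodes for $\beta < 0$, unstable
for $\beta > 0$).  The remaining six are degenerate at every accessible
order of the radial expansion, so `classify_equator_equilibrium()`
classifies them *constructively*: the equator flow direction
$G_4(\theta) = \cos\theta\,Q_3(\cos\theta,\sin\theta)$ on either side
(counterclockwise iff $G_4 > 0$), combined with a short integration of
the desingularised flow started just inside the hemisphere
(forward-time probe for a candidate stable node, backward-time for a
candidate unstable node; probe height $Z_0 = 0.02$, horizon 20 rescaled
time units with $\times 10$ and $\times 100$ retries, approach/departure
thresholds 0.8 and 3).  Mixed evidence yields `saddle`; an integrator
failure yields an explicit `undetermined`, never a guess.  Because the
interior direction of these points is infinitely degenerate, the
finite-height probe reports the dominant finite-time behaviour; at very
small probe heights the equator attraction of the diagonal points can
dominate their weak interior repulsion.

### The heteroclinic threshold $\gamma^*$

When $\alpha\beta < 0$ the stable limit cycle grows with $\gamma$ and is
destroyed at a critical $\gamma^*$ where it becomes a heteroclinic cycle
through four saddles at infinity; the period diverges like
$T(\gamma) = A - B\log(\gamma^* - \gamma)$.  `estimate_gamma_star()`
continues the stable branch (through its fold first when the Hopf is
subcritical), terminates on the blow-up signature — period above
`T_max` (default 1000 s), amplitude above `R_max` (default $10^3$), or
stalling of $\gamma$ while $T$ grows (tolerance $10^{-9}$) — and fits the
logarithmic law on the monotone tail by profiling $\gamma^*$
(one-dimensional minimisation of the least-squares residual; $A$, $B$
enter linearly).  The reported value is the fitted asymptote; the bracket
lower end is the last resolved branch point.  In practice the arclength
steps make $\gamma^* - \gamma$ shrink geometrically, so the branch
resolves the law over many decades and the fit is sharp (the suite
checks $R^2 > 0.95$ and agreement of asymptote and bracket within
$10^{-3}$).

## Continuation by orthogonal collocation

Periodic orbits are discretised on $[0,1]$ (time scaled by the period)
with `NTST = 50` mesh intervals carrying degree-`NCOL = 4` Lagrange
polynomials through equally spaced representation points, collocated at
the interval Gauss points; unknowns are the profile values, the period
and the free parameter; equations are collocation, periodicity, an
integral phase condition (orthogonality to the previous profile's time
derivative) and one closure row.  Newton iterates to $10^{-9}$.  These
settings mirror standard practice for this model family, so bifurcation
coordinates are comparable with published values.  The closure row is

* fixed parameter (converging a seed orbit),
* fixed amplitude (starting from a Hopf point: the eigenplane orbit
  $u = \varepsilon(\mathrm{Re}\,q\cos 2\pi t - \mathrm{Im}\,q\sin 2\pi t)$
  is corrected with the parameter free, and a second solve at
  $2\varepsilon$ provides the secant tangent, which orients the branch
  away from zero amplitude without guessing the criticality), or
* pseudo-arclength, with an integral inner product on the profile part,
  weight 0 on the period and weight 1 on the parameter.

Step control multiplies the step by 1.4 / divides by 1.5 on Newton
iteration counts $\le 3$ / $\ge 6$, with $h \in [10^{-5}, 0.1]$; failed
steps are halved.  Optional mesh adaptation re-equidistributes profile
arclength (blended 50/50 with the old mesh) and re-converges at fixed
parameter; it is essential near heteroclinic tails.

**Floquet multipliers** come from condensing the linearised collocation
system interval by interval into transfer matrices whose ordered product
is the monodromy; the trivial multiplier then reproduces 1 to $10^{-6}$
or better along well-resolved branches (the suite asserts this), which is
the practical resolution guard.  For manifold-reduced branches the
multipliers are computed for the full 4D system along the embedded orbit,
so within-manifold folds and transverse symmetry breaking are both seen.

**Detection.**  Folds flip the sign of the parameter component of the
branch tangent; branch points flip
$\prod(\mu_i - 1)$ over non-trivial multipliers without a fold; period
doublings flip $\prod(\mu_i + 1)$.  Sign changes are localised by
bisection along the branch (tolerance $10^{-8}$ on the test function).
Multiplier-based tests are suppressed when the monodromy is numerically
extreme (any $|\mu| > 10^6$, or trivial multiplier off by more than
$10^{-3}$), which happens on near-heteroclinic tails where the products
flip on round-off; duplicate records within $10^{-6}$ in the parameter
are merged.  Branch-point labels (e.g. BP$_{\rm AL}$ vs BP$_{\rm AA}$)
are assigned by actually switching onto the bifurcating family and
following it a short way — the lag leaves the symmetric value
continuously, so the instantaneous lag at the branch point itself cannot
classify it.

**Branch switching** frees the parameter and pins the projection of the
deviation onto the critical Floquet eigenfunction (propagated along the
orbit through the same interval transfer matrices); at a pitchfork this
forces Newton off the symmetric branch while the parameter relaxes to the
side where the new family exists.  Period-doubling switches duplicate the
mesh and apply the eigenfunction antiperiodically.  Fixed-parameter
correction from a perturbed profile — the naive approach — simply falls
back onto the symmetric orbit and is not used.

**Two-parameter fold loci** are grids of one-parameter runs (each
started from the anti-phase Hopf point and stopped at its first fold),
which is simpler and directly testable; the extended-system alternative
was not needed at the problem sizes used.

## Time stepping, phases, regimes

`simulate()` integrates compiled right-hand sides via `deSolve`
(`lsodar`), with defaults `rtol = 1e-8`, `atol = 1e-10` — tight enough to
resolve phase lags below a degree — and a root function that terminates
cleanly when any component exceeds `R_max = 10^3`.  Divergence is a
reported outcome (`meta$diverged`, label `diverged`), not an exception,
because blow-up is meaningful in this model; strict callers can set
`tolerate_blowup = FALSE` to get a typed `hkb_blowup_error` carrying the
last state.  The default transient marker is `min(200, span/2)` time
units.

The relative phase follows the peak-time convention: $t_i$ is the time of
the maximum of $x_i$ within one period (quadratic interpolation around
sample maxima; the first $x_1$ peak after the transient anchors the
measurement), the period is the mean $x_1$ peak spacing (relative jitter
above 1% raises a typed aperiodicity error), and the signed lag is
$360^\circ\,(t_2 - t_1)/T$ mapped to $(-180^\circ, 180^\circ]$ — positive
when oscillator 2 is delayed.  This sign convention is a package
convention chosen to make the bistable-regime studies read naturally
("$x_2$ delayed by $\approx 90^\circ$"); the folded value
$|{\rm lag}| \in [0^\circ, 180^\circ]$ is what classification and
histogramming use unless a signed distribution is requested.
Classification bins are `tol_phase = 5°` around $0^\circ$ and
$180^\circ$, amplitude floor $10^{-4}$ for `steady`, amplitude-ratio
deviation 0.05 for the asymmetric-amplitude flag, and `chaotic` requires
an aperiodic window plus a Benettin largest Lyapunov exponent above 0.01
and above twice its standard error.  All are configurable.

## Scenarios and the synthetic-experiment layer

`get_scenario()` returns the named parameter sets of the study designs
(per figure of the source analyses), each carrying a provenance note.
Three registry decisions deserve mention, all recorded in the notes
field:

* the bistability/hysteresis scenario stores $b = -0.5$ although the
  printed legend says $b = 0.5$: with $b = +0.5$ the anti-phase reduced
  oscillator at those parameters is past its heteroclinic threshold and
  *every* trajectory off the in-phase manifold diverges, so none of the
  quoted observations is reproducible, while $b = -0.5$ (the quadrant
  where phase-locked solutions are stable) reproduces all of them;
* the sweep-in-$a$ scenario stores $\alpha = \beta = 1$, the
  self-consistent reading of a legend that also prints "$a=b=1$";
* the frequency-ratio scenario defaults to the fourth-quadrant setting
  $a = 0.5$, $b = -0.5$ (its source says "second quadrant", where
  phase-locked solutions are unstable; the discrepancy is flagged).

The normal-distribution sampler for the uncertainty study uses mean
0.125 and sd 0.025 (centre and quarter-width of the printed uniform
support), since no values are printed.  Per-draw initial conditions are
fresh seeded uniform draws on $[-0.5, 0.5]^4$ (the origin excluded), and
every draw gets a 220-time-unit transient before a 60-unit analysis
window; draws that diverge or fail the periodicity check are counted and
excluded from the histogram.  Histogram bins are $5^\circ$; modes are
local maxima with prominence at least 5% of the draw count.

Because the in-phase state is unstable for every $a > 0$ (see above),
the folded-lag distribution for $a \sim U(0.05, 0.2)$ concentrates at
$180^\circ$ with a ramp of phase-locked lags below it and has **no mode
at $0^\circ$**; the acceptance test that asserts such a mode is expected
to fail and documents this.  A protocol that starts each draw near the
in-phase state and measures within a finite window would record
$0^\circ$ for small $a$ (the transverse multiplier at $a = 0.05$ is only
$\approx 1.17$ per period), which is the plausible origin of published
histograms with a $0^\circ$ peak; the package deliberately measures
attractors, not transients.

Quasi-static sweeps integrate continuously while the parameter moves
through plateaus (default 40 per pass, 100 settle + 50 analysis time
units), carrying the state across updates — the mechanism that produces
hysteresis.  Jumps are folded-lag discontinuities above $30^\circ$
between successive *resolved* plateaus (a window flagged as aperiodic
during the transition does not break the comparison); hysteresis means
forward and backward passes disagree by more than $20^\circ$ at equal
parameter values.  Near a fold, critical slowing can delay the observed
jump by about one plateau.

The frequency-ratio study fixes $\omega_1$ and continues in
$r = \omega_1/\omega_2$ from the identical case, where the in-phase
orbit is the single-oscillator cycle.  Signed-lag antisymmetry under
$r \mapsto 1/r$ combined with the oscillator swap holds exactly only to
leading order in $\log r$ (the fixed-$\omega_1$ slice is not itself
swap-invariant: the swap lands on a time-rescaled system); the suite
asserts it within $1^\circ$ for $|r - 1| \le 0.04$.

## Problem sizes and limitations

The suite and the acceptance script run at deliberately modest sizes
chosen to keep every computation well inside interactive tolerances while
leaving the detection machinery fully exercised: uncertainty studies use
200 seeded draws (the registry records the full 2000-draw design),
bistability scans use small grids with 6–10 initial conditions per cell,
Lyapunov estimates use 300 renormalisation intervals, and continuation
runs use at most a few hundred accepted points.

Known limitations:

* the generator emulates the study designs (fixed parameter sets, seeded
  samplers, random initial conditions); it does not emulate measurement
  noise, stochastic forcing or human-data artefacts, so passing tests
  say nothing about fitting real movement recordings;
* the chaotic regime of the period-doubling scenario at high damping is
  metastable (a chaotic set with escape), so Lyapunov estimates there
  depend on staying in the bounded phase; the estimator raises a typed
  blow-up error when the trajectory escapes rather than reporting a
  number;
* torus bifurcations, homoclinic/heteroclinic continuation, and
  compactification of the full 4D system are out of scope;
* equator classification of the infinitely degenerate points reports
  dominant finite-time behaviour, as discussed above.
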