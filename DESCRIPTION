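Package: hkbdyn
Title: Bifurcation and Coordination-Regime Analysis of the Haken-Kelso-Bunz
    Coupled-Oscillator Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the full four-dimensional analysis of the
    Haken-Kelso-Bunz (HKB) model of rhythmic movement coordination: vector
    fields and Jacobians for the single, coupled-identical and
    coupled-heterogeneous hybrid Rayleigh-Van der Pol oscillators;
    closed-form linear stability and Hopf criticality of the trivial state;
    Poincare-sphere compactification with classification of equilibria at
    infinity and estimation of the critical damping at which limit cycles
    are destroyed in a heteroclinic transition; pseudo-arclength
    continuation of equilibria and periodic orbits by orthogonal collocation
    with Floquet-based stability and detection of Hopf, fold,
    symmetry-breaking and period-doubling bifurcations; relative-phase
    computation and coordination-regime classification; and composite
    numerical experiments (uncertainty quantification of phase-lag
    distributions, quasi-static hysteresis sweeps, frequency-ratio studies
    and bistability scans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
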