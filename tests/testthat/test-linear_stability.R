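test_that("trivial equilibrium classification follows the case analysis", {
  cases <- list(
    list(g = -1, kind = "stable focus"),
    list(g = 1, kind = "unstable focus"),
    list(g = -5, kind = "stable node"),
    list(g = 5, kind = "unstable node"),
    list(g = 0, kind = "non-hyperbolic"),
    list(g = 4, kind = "non-hyperbolic"),   # gamma == 2*omega exactly
    list(g = -4, kind = "non-hyperbolic"))
  for (cs in cases) {
    cl <- classify_trivial_single(osc_params(1, 1, cs$g, 2))
    expect_identical(cl$kind, cs$kind)
    # eigenvalues must satisfy the characteristic polynomial
    lam <- cl$eigenvalues
    expect_lt(max(Mod(lam^2 - cs$g * lam + 4)), 1e-10)
  }
})

test_that("first Lyapunov coefficient and criticality follow the closed form", {
  h <- hopf_criticality_single(osc_params(1, 1, 0, 2))
  expect_equal(h$l1, -13 / 20)
  expect_identical(h$label, "supercritical")
  expect_equal(h$transversality, 0.5)
  h2 <- hopf_criticality_single(osc_params(1, -0.1, 0, 2))
  expect_identical(h2$label, "subcritical")
  expect_gt(h2$l1, 0)
  h3 <- hopf_criticality_single(osc_params(-1, 1, 0, 2))
  expect_identical(h3$label, "supercritical")
  hd <- hopf_criticality_single(osc_params(-12, 1, 0, 2))  # alpha = -3 beta w^2
  expect_identical(hd$label, "degenerate")
})

test_that("coupled-origin spectrum factorises and is b-independent", {
  sp <- origin_spectrum_coupled(coupled_params(1, 1, 0, 2, a = 0, b = 0.5))
  expect_equal(sort(Im(sp$eigenvalues)), c(-2, -2, 2, 2))
  expect_lt(max(abs(Re(sp$eigenvalues))), 1e-12)
  set.seed(5)
  for (k in 1:20) {
    pars <- coupled_params(runif(1, -1, 1), runif(1, -1, 1), runif(1, -2, 2),
                           omega = runif(1, 0.5, 3), a = runif(1, -1, 1),
                           b = runif(1, -2, 2))
    sp <- origin_spectrum_coupled(pars)
    fac <- c(sp$mode_factors$`in-phase`$eigenvalues,
             sp$mode_factors$`anti-phase`$eigenvalues)
    d <- sapply(sp$eigenvalues, function(ev) min(Mod(fac - ev)))
    expect_lt(max(d), 1e-10)
    # factors do not involve b
    sp2 <- origin_spectrum_coupled(set_b(pars, pars$b + 1))
    expect_equal(sp$mode_factors$`anti-phase`$trace,
                 sp2$mode_factors$`anti-phase`$trace)
  }
})

test_that("analytic Hopf loci match numerically detected Hopf points", {
  expect_equal(unname(hopf_loci(0.5)), c(0, -1))
  expect_equal(unname(hopf_loci(0)), c(0, 0))
  expect_equal(unname(hopf_loci(-0.5)), c(0, 1))
  for (a in c(-0.5, 0.5)) for (b in c(-0.5, 0.5)) {
    eb <- continue_equilibrium_branch(
      coupled_params(1, 1, 0, 2, a = a, b = b), "gamma",
      range = c(-2 * abs(a) - 0.6, 2 * abs(a) + 0.6), nsteps = 60)
    got <- sort(vapply(eb$bifurcations, `[[`, 0, "par_value"))
    expect_equal(got, sort(unname(hopf_loci(a))), tolerance = 1e-6)
  }
})

test_that("heterogeneous origin returns untagged full spectrum", {
  sp <- origin_spectrum_coupled(coupled_params(1, 1, 0.3, omega1 = 2,
                                               omega2 = 1.5, a = 0.2, b = 0.1))
  expect_null(sp$mode_factors)
  expect_length(sp$eigenvalues, 4)
})
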