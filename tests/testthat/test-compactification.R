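test_that("sphere projection is a bijection onto the upper hemisphere", {
  expect_equal(unname(sphere_project(0, 0)), c(0, 0, 1))
  expect_equal(unname(sphere_project(1, 0)), c(1 / sqrt(2), 0, 1 / sqrt(2)))
  set.seed(7)
  for (k in 1:1000) {
    u <- runif(2, -50, 50)
    s <- sphere_project(u[1], u[2])
    expect_lt(abs(sum(s^2) - 1), 1e-12)
    expect_lt(max(abs(sphere_unproject(s) - u)), 1e-12 * max(1, abs(u)))
  }
  expect_error(sphere_unproject(c(X = 1, Y = 0, Z = 0)),
               class = "hkb_infinity_error")
  expect_error(sphere_project(Inf, 0), class = "hkb_blowup_error")
})

test_that("compactified field is tangent and conjugate to the planar flow", {
  p <- osc_params(-1, 1, 1, 2)
  set.seed(8)
  # tangency of both variants
  for (k in 1:50) {
    u <- runif(2, -3, 3)
    s <- sphere_project(u[1], u[2])
    expect_lt(abs(sum(s * compactified_rhs(s, p))), 1e-10)
    expect_lt(abs(sum(s * compactified_rhs(s, p, desingularized = TRUE))),
              1e-10)
  }
  expect_error(compactified_rhs(c(1, 0, 0), p), class = "hkb_infinity_error")
  expect_equal(unname(compactified_rhs(c(0, 0, 1), p)), c(0, 0, 0))
  # trajectories of the compactified flow project onto planar trajectories
  f <- function(t, s, parms) list(compactified_rhs(s, p))
  for (k in 1:20) {
    u0 <- runif(2, -1, 1)
    tr <- simulate(p, u0, 10, opts = list(dt = 0.1, t_transient = 0,
                                          rtol = 1e-10, atol = 1e-12))
    out <- deSolve::ode(sphere_project(u0[1], u0[2]), seq(0, 10, by = 0.1),
                        f, NULL, rtol = 1e-10, atol = 1e-12)
    back <- t(apply(out[, 2:4], 1, function(s) s[1:2] / s[3]))
    expect_lt(max(abs(back - tr$states)), 1e-6)
  }
})

test_that("equator equilibria: count, residuals and brute-force agreement", {
  grid <- list(c(-1, 1), c(1, -0.1), c(1, 1), c(-2, -0.5), c(0.3, 2))
  for (ab in grid) {
    e <- equator_equilibria(ab[1], ab[2])
    expect_length(e, if (ab[1] * ab[2] < 0) 8 else 4)
    th <- vapply(e, `[[`, 0, "theta")
    expect_lt(max(abs(equator_flow(th, ab[1], ab[2]))), 1e-10)
    # independent root scan over a fine theta grid
    brute <- equator_roots_bruteforce(ab[1], ab[2])
    expect_equal(sort(th), brute, tolerance = 1e-8)
  }
  # diagonal coordinates for the subcritical figure case
  e <- equator_equilibria(1, -0.1)
  X <- sort(unique(round(abs(vapply(e, `[[`, 0, "X")), 6)))
  expect_equal(X, round(c(0, sqrt(0.1 / 1.1), 1), 6))
  Y <- sort(unique(round(abs(vapply(e, `[[`, 0, "Y")), 6)))
  expect_equal(Y, round(c(0, sqrt(1 / 1.1), 1), 6))
  expect_error(equator_equilibria(0, 0), "degenerate")
})

test_that("equator flow has the printed value and fixed sign between roots", {
  expect_equal(equator_flow(0, 1, 1), 0)
  expect_equal(equator_flow(pi / 4, 1, 1), -0.5)
  e <- equator_equilibria(-1, 1)
  th <- sort(vapply(e, `[[`, 0, "theta"))
  for (i in seq_along(th)) {
    lo <- th[i]; hi <- if (i < length(th)) th[i + 1] else th[1] + 2 * pi
    mid <- seq(lo + 1e-3, hi - 1e-3, length.out = 9)
    s <- sign(equator_flow(mid, -1, 1))
    expect_true(all(s == s[1]))
  }
})

test_that("equilibria at infinity are classified as in the global portraits", {
  e_sup <- equator_equilibria(-1, 1)
  p_sup <- osc_params(-1, 1, 3.6, 2)     # just below the transition
  types <- vapply(e_sup, classify_equator_equilibrium, "", params = p_sup)
  axisY <- vapply(e_sup, function(e) e$hyperbolic, TRUE)
  expect_true(all(types[axisY] == "unstable node"))   # beta > 0
  axisX <- vapply(e_sup, function(e) abs(abs(e$X) - 1) < 1e-9, TRUE)
  expect_true(all(types[axisX] == "saddle"))
  e_sub <- equator_equilibria(1, -0.1)
  p_sub <- osc_params(1, -0.1, -0.03, 2)
  types2 <- vapply(e_sub, classify_equator_equilibrium, "", params = p_sub)
  hyp <- vapply(e_sub, function(e) e$hyperbolic, TRUE)
  expect_true(all(types2[hyp] == "stable node"))      # beta < 0
  expect_true(all(types2[!hyp] %in% c("saddle", "unstable node")))
  expect_equal(sum(types2 == "unstable node"), 2)
})
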