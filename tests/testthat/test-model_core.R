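test_that("vector field matches hand-evaluated values", {
  p <- osc_params(1, 1, 1, 2)
  expect_equal(unname(hkb_rhs(c(0, 0), p)), c(0, 0))
  expect_equal(unname(hkb_rhs(c(1, 1), p)), c(1, -5))
  cp <- coupled_params(1, 1, 1, 2, a = 0.5, b = -0.5)
  expect_equal(unname(hkb_rhs(c(0, 0, 0, 0), cp)), c(0, 0, 0, 0))
})

test_that("coupling terms are antisymmetric and match direct evaluation", {
  expect_equal(unname(coupling_terms(c(0.3, 0.7, 1, 1), a = 2, b = -1)),
               c(0, 0))
  expect_equal(unname(coupling_terms(c(0.4, 0.4, 1.5, -0.5), a = 0.5, b = 9)),
               c(1, -1))
  for (u in random_states(50, 4, scale = 2, seed = 3)) {
    ct <- coupling_terms(u, a = 0.7, b = -1.3)
    expect_equal(unname(ct[1] + ct[2]), 0)
  }
})

test_that("Jacobian is analytic-exact against finite differences", {
  p <- osc_params(0.7, -0.3, 1.2, 1.7)
  cp <- coupled_params(1.1, 0.4, -0.6, omega1 = 2, omega2 = 1.4,
                       a = 0.45, b = -0.8)
  expect_equal(hkb_jacobian(c(0, 0), osc_params(1, 1, 1, 2)),
               matrix(c(0, -4, 1, 1), 2, 2))
  for (u in random_states(50, 2, seed = 11))
    expect_lt(max(abs(hkb_jacobian(u, p) - fd_jacobian(u, p))), 1e-6)
  for (u in random_states(50, 4, seed = 12))
    expect_lt(max(abs(hkb_jacobian(u, cp) - fd_jacobian(u, cp))), 1e-6)
})

test_that("field is odd and swap-equivariant for identical oscillators", {
  cp <- coupled_params(0.8, 1.2, 0.9, 2, a = 0.3, b = 0.6)
  p <- osc_params(0.8, 1.2, 0.9, 2)
  swap <- function(u) u[c(2, 1, 4, 3)]
  for (u in random_states(40, 4, scale = 1.5, seed = 21)) {
    expect_equal(hkb_rhs(-u, cp), -hkb_rhs(u, cp))
    expect_equal(hkb_rhs(swap(u), cp), swap(hkb_rhs(u, cp)))
  }
  for (u in random_states(20, 2, scale = 1.5, seed = 22))
    expect_equal(hkb_rhs(-u, p), -hkb_rhs(u, p))
})

test_that("invalid parameters and non-finite states are rejected", {
  expect_error(osc_params(1, 1, 1, 0), "omega")
  expect_error(osc_params(1, 1, NA, 2), "finite")
  expect_error(coupled_params(1, 1, 1, omega1 = 2, omega2 = -1, a = 0, b = 0),
               "omega")
  p <- osc_params(1, 1, 1, 2)
  expect_error(hkb_rhs(c(Inf, 0), p), class = "hkb_blowup_error")
  err <- tryCatch(hkb_rhs(c(0, NaN), p), error = identity)
  expect_s3_class(err, "hkb_blowup_error")
  expect_true(!is.finite(err$state[2]))
  expect_error(hkb_rhs(c(1, 2, 3), p), "length")
})

test_that("heterogeneous eigenfrequencies enter per oscillator", {
  cp <- coupled_params(1, 1, 0, omega1 = 2, omega2 = 3, a = 0, b = 0)
  f <- hkb_rhs(c(1, 1, 0, 0), cp)
  expect_equal(unname(f), c(0, 0, -4, -9))
})
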