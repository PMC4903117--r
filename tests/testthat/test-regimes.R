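test_that("relative phase recovers known lags of synthetic sinusoids", {
  t <- seq(0, 60, by = 0.005)
  for (d in c(0.1, 0.5, 1.0, 2.0)) {
    rp <- relative_phase(sin(t), sin(t - d), t)
    expect_equal(rp$lag, d * 180 / pi, tolerance = 0.5 / (d * 180 / pi) + 0.01)
    expect_lt(abs(rp$lag - d * 180 / pi), 0.5)
  }
  expect_equal(relative_phase(sin(t), sin(t), t)$lag, 0, tolerance = 1e-6)
  expect_equal(abs(relative_phase(sin(t), -sin(t), t)$lag), 180,
               tolerance = 1e-4)
})

test_that("lag transforms correctly under oscillator swap", {
  t <- seq(0, 60, by = 0.005)
  x1 <- sin(t); x2 <- sin(t - 0.8)
  a <- relative_phase(x1, x2, t)
  b <- relative_phase(x2, x1, t)
  expect_equal(a$folded, b$folded, tolerance = 1e-2)
  expect_equal(a$lag, -b$lag, tolerance = 1e-2)
})

test_that("aperiodic windows raise a typed error", {
  t <- seq(0, 60, by = 0.005)
  set.seed(2)
  x <- sin(t * (1 + 0.2 * sin(0.3 * t)))
  expect_error(relative_phase(x, x, t), class = "hkb_aperiodic_error")
})

test_that("regimes classify by folded-lag bins, amplitude and divergence", {
  # steady decay to the origin for gamma < 0
  tr <- simulate(osc_params(1, 1, -0.5, 2), c(0.3, 0), 120,
                 opts = list(t_transient = 100))
  expect_identical(classify_regime(tr)$label, "steady")
  # anti-phase is the only stable state in the first quadrant
  p1 <- coupled_params(1, 1, 0.5, 2, a = 0.5, b = 0.5)
  set.seed(3)
  tr1 <- simulate(p1, runif(4, -0.5, 0.5), 300, opts = list(t_transient = 240))
  expect_identical(classify_regime(tr1)$label, "anti-phase")
  # in-phase is stable in the third quadrant
  p3 <- coupled_params(1, 1, 0.5, 2, a = -0.5, b = -0.5)
  tr3 <- simulate(p3, runif(4, -0.5, 0.5), 300, opts = list(t_transient = 240))
  expect_identical(classify_regime(tr3)$label, "in-phase")
  # divergence is a label, not an exception
  pq1 <- coupled_params(1, 1, 1, 2, a = 0.5, b = 0.5)
  trd <- simulate(pq1, c(0.4, -0.2, 0.1, 0.3), 300)
  expect_identical(classify_regime(trd)$label, "diverged")
  # phase-locked attractor with asymmetric amplitudes (Fig 11 setting)
  pf <- coupled_params(-1.7, 0.5, 1.7, 2.3, a = 0.5, b = -0.5)
  trf <- simulate(pf, fig11_pl_ic, 350, opts = list(t_transient = 280))
  cl <- classify_regime(trf)
  expect_identical(cl$label, "phase-locked")
  expect_equal(cl$folded_lag, 85, tolerance = 2)
  expect_true(cl$asymmetric)
})

test_that("attractor enumeration merges and counts basins", {
  # single stable origin (the slowest eigenmode decays at rate (gamma+2a)/2
  # = -0.05, so the settle time must outlast it)
  p0 <- coupled_params(1, 1, -0.5, 2, a = 0.2, b = 0.2)
  att0 <- enumerate_attractors(p0, random_initial_conditions(4, 5, 0.3),
                               opts = list(t_end = 450, t_transient = 400))
  expect_length(att0, 1)
  expect_identical(att0[[1]]$label, "steady")
  # a point-mass ic set yields exactly one attractor
  p1 <- coupled_params(1, 1, 0.5, 2, a = 0.5, b = 0.5)
  att1 <- enumerate_attractors(p1, list(c(0.3, -0.2, 0.1, 0.2)))
  expect_length(att1, 1)
  # bistability at the Fig 11 point: anti-phase + phase-locked (+- pair)
  pf <- coupled_params(-1.7, 0.5, 1.7, 2.3, a = 0.5, b = -0.5)
  att <- enumerate_attractors(pf, random_initial_conditions(12, 42, 1))
  labs <- vapply(att, `[[`, "", "label")
  expect_true("anti-phase" %in% labs)
  expect_true("phase-locked" %in% labs)
  pl <- att[[which(labs == "phase-locked")[1]]]
  expect_length(pl$lag_signs, 2)
})

test_that("largest Lyapunov exponent separates attractor types", {
  ly_eq <- max_lyapunov(osc_params(1, 1, -0.5, 2), c(0.2, 0),
                        opts = list(n_renorm = 100, t_transient = 20))
  expect_lt(ly_eq$exponent, 0)
  ly_po <- max_lyapunov(coupled_params(1, 1, 0.5, 2, a = 0.5, b = 0.5),
                        c(0.3, -0.3, 0, 0), opts = list(n_renorm = 150))
  expect_lt(ly_po$exponent, 2 * ly_po$se)
  expect_error(
    max_lyapunov(coupled_params(1, 1, 1, 2, a = 0.5, b = 0.5),
                 c(0.4, -0.2, 0.1, 0.3),
                 opts = list(n_renorm = 20, t_transient = 50)),
    class = "hkb_blowup_error")
})

test_that("classification is stable under halved solver tolerances", {
  panel <- list(
    list(p = coupled_params(1, 1, 0.5, 2, a = 0.5, b = 0.5),
         ic = c(0.3, -0.2, 0.1, 0.2)),
    list(p = coupled_params(1, 1, 0.5, 2, a = -0.5, b = -0.5),
         ic = c(0.3, 0.25, 0, 0.1)),
    list(p = coupled_params(-1.7, 0.5, 1.7, 2.3, a = 0.5, b = -0.5),
         ic = fig11_pl_ic),
    list(p = osc_params(1, 1, -0.5, 2), ic = c(0.2, 0)))
  for (cs in panel) {
    l1 <- classify_regime(simulate(cs$p, cs$ic, 300,
                                   opts = list(t_transient = 240)))$label
    l2 <- classify_regime(simulate(cs$p, cs$ic, 300,
                                   opts = list(t_transient = 240,
                                               rtol = 5e-9, atol = 5e-11)))$label
    expect_identical(l1, l2)
  }
})
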