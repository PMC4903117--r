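test_that("equilibrium continuation locates Hopf points of both systems", {
  eb <- continue_equilibrium_branch(osc_params(1, 1, 0, 2), "gamma", c(-1, 2))
  expect_length(eb$bifurcations, 1)
  expect_lt(abs(eb$bifurcations[[1]]$par_value), 1e-8)
  expect_equal(eb$bifurcations[[1]]$im, 2, tolerance = 1e-6)
  expect_true(all(eb$points$norm == 0))   # trivial branch is x == 0
  eb2 <- continue_equilibrium_branch(
    coupled_params(1, 1, 0, 2, a = 0.5, b = 0.5), "gamma", c(-2, 1))
  pars <- sort(vapply(eb2$bifurcations, `[[`, 0, "par_value"))
  expect_equal(pars, c(-1, 0), tolerance = 1e-7)
  modes <- vapply(eb2$bifurcations, `[[`, "", "mode")
  expect_setequal(modes, c("anti-phase", "in-phase"))
})

test_that("Hopf-emanating orbits have the linearisation period and phase", {
  p <- osc_params(1, 1, 0, 2)
  eb <- continue_equilibrium_branch(p, "gamma", c(-0.5, 0.5))
  orb <- orbit_from_hopf(eb$bifurcations[[1]], p, "gamma", eps = 1e-3)
  expect_equal(orb$period, pi, tolerance = 0.01)
  cp <- coupled_params(1, 1, 0, 2, a = 0.5, b = 0.5)
  brA <- coupled_mode_branch(cp, "antiphase", "gamma", c(-1.2, -0.8),
                             opts = list(max_steps = 5,
                                         compute_floquet = FALSE))
  orbA <- brA$points[[2]]$orbit
  expect_equal(abs(hkbdyn:::orbit_lag(orbA)), 180)
  brI <- coupled_mode_branch(cp, "inphase", "gamma", c(-0.2, 0.3),
                             opts = list(max_steps = 5,
                                         compute_floquet = FALSE))
  expect_equal(hkbdyn:::orbit_lag(brI$points[[2]]$orbit), 0)
  # degenerate Hopf is refused
  expect_error(
    coupled_mode_branch(coupled_params(1, 1, 0, 2, a = 0.5, b = 13 / 8),
                        "antiphase", "gamma", c(-1.2, -0.8)),
    "degenerate")
})

test_that("orbit amplitude grows as sqrt(gamma) at a supercritical Hopf", {
  p <- osc_params(1, 1, 0, 2)
  eb <- continue_equilibrium_branch(p, "gamma", c(-0.5, 0.5))
  orb <- orbit_from_hopf(eb$bifurcations[[1]], p, "gamma", eps = 2e-4)
  br <- continue_periodic_branch(orb, "gamma", c(-1e-5, 0.02),
                                 opts = list(ds0 = 2e-4, ds_max = 2e-3,
                                             max_steps = 80,
                                             compute_floquet = FALSE))
  df <- branch_points_df(br)
  sel <- df$par > 1e-4 & df$par < 1e-2
  expect_gt(sum(sel), 5)
  slope <- coef(lm(log(df$max_abs_1[sel]) ~ log(df$par[sel])))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.05)
})

test_that("branch direction and orbit stability reflect Hopf criticality", {
  # subcritical: small orbits exist for gamma < 0 and are unstable
  p <- osc_params(1, -0.1, 0, 2)
  eb <- continue_equilibrium_branch(p, "gamma", c(-0.5, 0.5))
  orb <- orbit_from_hopf(eb$bifurcations[[1]], p, "gamma", eps = 1e-3)
  br <- continue_periodic_branch(orb, "gamma", c(-0.2, 0.1),
                                 opts = list(ds0 = 5e-3, max_steps = 25))
  df <- branch_points_df(br)
  early <- df[df$par < -1e-4 & df$max_abs_1 < 0.5, ]
  expect_gt(nrow(early), 3)
  expect_true(all(!early$stable))
  # supercritical: orbits for gamma > 0, stable
  p2 <- osc_params(1, 1, 0, 2)
  eb2 <- continue_equilibrium_branch(p2, "gamma", c(-0.5, 0.5))
  orb2 <- orbit_from_hopf(eb2$bifurcations[[1]], p2, "gamma", eps = 1e-3)
  br2 <- continue_periodic_branch(orb2, "gamma", c(-0.1, 0.3),
                                  opts = list(ds0 = 5e-3, max_steps = 25))
  df2 <- branch_points_df(br2)
  expect_true(all(df2$par > -1e-6))
  expect_true(all(df2$stable[df2$par > 1e-4]))
})

test_that("trivial Floquet multiplier is 1 on every accepted orbit", {
  p <- osc_params(1, 1, 0, 2)
  eb <- continue_equilibrium_branch(p, "gamma", c(-0.5, 0.5))
  orb <- orbit_from_hopf(eb$bifurcations[[1]], p, "gamma")
  br <- continue_periodic_branch(orb, "gamma", c(-0.1, 2),
                                 opts = list(max_steps = 30))
  tm <- vapply(br$points, function(pt) abs(pt$trivial_mult - 1), 0)
  expect_lt(max(tm), 1e-6)
})

test_that("symmetry-breaking branch points are detected and classified", {
  # fourth quadrant: BP_AL on the anti-phase branch, switching yields the
  # stable phase-locked family with lag strictly inside (0, 180)
  p4 <- coupled_params(1, 1, 0, 2, a = 0.5, b = -0.5)
  br4 <- coupled_mode_branch(p4, "antiphase", "gamma", c(-1.5, 3),
                             opts = list(max_steps = 120, stop_at = "BP"))
  bps <- Filter(function(b) b$kind == "BP", br4$bifurcations)
  expect_gte(length(bps), 1)
  bp <- bps[[1]]
  expect_equal(bp$par_value, 2.248, tolerance = 1e-3)
  sw <- switch_branch(bp, eps = 1e-2)
  brL <- continue_periodic_branch(sw, "gamma", c(0, 4),
                                  opts = list(max_steps = 25, ds0 = 0.03))
  lag <- abs(hkbdyn:::orbit_lag(brL$points[[length(brL$points)]]$orbit))
  expect_gt(lag, 5); expect_lt(lag, 175)
  # third quadrant: BP_AA on the (unstable) anti-phase branch
  p3 <- coupled_params(1, 1, 0, 2, a = -0.5, b = -0.5)
  br3 <- coupled_mode_branch(p3, "antiphase", "gamma", c(0.5, 3),
                             opts = list(max_steps = 120, stop_at = "BP",
                                         classify_bp = TRUE))
  labs3 <- vapply(br3$bifurcations, `[[`, "", "label")
  expect_true("BP_AA" %in% labs3)
  # first quadrant: BP_II on the unstable in-phase branch
  p1 <- coupled_params(1, 1, 0, 2, a = 0.5, b = 0.5)
  br1 <- coupled_mode_branch(p1, "inphase", "gamma", c(-0.5, 2),
                             opts = list(max_steps = 120, stop_at = "BP",
                                         classify_bp = TRUE))
  labs1 <- vapply(br1$bifurcations, `[[`, "", "label")
  expect_true("BP_II" %in% labs1)
})

test_that("stable branch points are reproduced by direct time stepping", {
  p4 <- coupled_params(1, 1, 2.6, 2, a = 0.5, b = -0.5)
  set.seed(1)
  tr0 <- simulate(p4, c(0.5, -0.1, 0.3, 0.4), 350,
                  opts = list(t_transient = 280))
  orb <- orbit_from_trajectory(tr0, p4, free = "gamma")
  expect_true(hkbdyn:::orbit_floquet(orb)$stable)
  # perturb and re-simulate: period and lag must match the orbit
  ic <- orb$profile[, 1] * 1.02
  tr <- simulate(p4, ic, 300, opts = list(t_transient = 240))
  w <- hkbdyn:::trajectory_window(tr)
  rp <- relative_phase(w$states[, 1], w$states[, 2], w$times)
  expect_equal(rp$period, orb$period, tolerance = 1e-3)
  expect_equal(rp$folded, abs(hkbdyn:::orbit_lag(orb)), tolerance = 2)
})

test_that("branch locations are robust under mesh refinement", {
  # fold of the subcritical single-oscillator branch, NTST 50 vs 100
  folds <- sapply(c(50, 100), function(ntst) {
    p <- osc_params(1, -0.1, 0, 2)
    eb <- continue_equilibrium_branch(p, "gamma", c(-0.5, 0.5))
    orb <- orbit_from_hopf(eb$bifurcations[[1]], p, "gamma", ntst = ntst)
    br <- continue_periodic_branch(orb, "gamma", c(-0.5, 0.1),
                                   opts = list(max_steps = 60,
                                               stop_at = "SN",
                                               compute_floquet = TRUE))
    sn <- Filter(function(b) b$kind == "SN", br$bifurcations)
    sn[[1]]$par_value
  })
  expect_lt(abs(diff(folds)), 1e-4)
})

test_that("two-parameter fold grid degenerates to one-parameter detection", {
  base <- coupled_params(1, 1, -1, 2, a = 0.5, b = 0)
  loc <- fold_locus_two_param(base, "gamma", "b", p2_values = 2.0)
  expect_equal(nrow(loc), 1)
  sn <- hkbdyn:::antiphase_fold(set_b(base, 2.0))
  expect_equal(loc$p1_sn[1], sn$par_value, tolerance = 1e-8)
})
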