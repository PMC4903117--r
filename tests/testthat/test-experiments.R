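test_that("a point-mass sampler yields a degenerate one-mode distribution", {
  sc <- get_scenario("fig7_uq_uniform")
  sp <- sampler_spec("a", "point", list(v = 0.1), n = 12, seed = 4)
  d <- uq_phase_distribution(sc, sampler = sp)
  expect_equal(d$n_excluded, 0)
  lags <- d$lags[is.finite(d$lags)]
  expect_lt(diff(range(lags)), 1)        # one deterministic lag
  expect_equal(nrow(d$modes), 1)
})

test_that("uq runs are reproducible and report exclusions", {
  sc <- get_scenario("fig7_uq_uniform")
  sp <- sampler_spec("a", "uniform", list(lo = 0.05, hi = 0.2),
                     n = 30, seed = 11)
  d1 <- uq_phase_distribution(sc, sampler = sp)
  d2 <- uq_phase_distribution(sc, sampler = sp)
  expect_identical(d1$lags, d2$lags)
  expect_identical(d1$histogram$counts, d2$histogram$counts)
  expect_equal(d1$n_excluded + sum(is.finite(d1$lags)), d1$n)
})

test_that("a constant schedule sweeps without jumps or hysteresis", {
  p <- coupled_params(-1.7, 0.5, 1.7, 2.3, a = 0.5, b = -0.5)
  sw <- quasi_static_sweep(p, schedule = list(param = "omega",
                                              values = rep(2.3, 6)),
                           opts = list(ic = fig11_pl_ic))
  expect_equal(nrow(sw$jumps), 0)
  expect_false(sw$hysteretic)
  lag <- sw$lag_folded[is.finite(sw$lag_folded)]
  expect_lt(diff(range(lag)), 1)
})

test_that("frequency-ratio continuation starts in phase and detects folds", {
  p <- coupled_params(1, 1, 1, 2, a = 0.5, b = -0.5)
  rs <- frequency_ratio_study(p, c(0.78, 1.28), opts = list(max_steps = 80))
  pts <- rs$points
  at1 <- pts[which.min(abs(pts$par - 1)), ]
  expect_lt(abs(at1$lag), 2)
  expect_gte(length(rs$folds), 1)
  # signed lag is antisymmetric under ratio inversion + swap near ratio 1
  # (use only the first monotone segment of each branch, before any fold)
  updf <- branch_points_df(rs$branch_up)
  upcut <- which(diff(updf$par) <= 0)[1]
  up <- updf[seq_len(if (is.na(upcut)) nrow(updf) else upcut), ]
  dndf <- branch_points_df(rs$branch_down)
  dncut <- which(diff(dndf$par) >= 0)[1]
  dn <- dndf[seq_len(if (is.na(dncut)) nrow(dndf) else dncut), ]
  for (r in c(1.02, 1.04)) {
    lu <- approx(up$par, up$lag, r)$y
    ld <- approx(dn$par, dn$lag, 1 / r)$y
    expect_lt(abs(lu + ld), 1)
  }
})

test_that("bistability scan marks the coexistence wedge", {
  p <- coupled_params(-1.7, 0.5, 1.7, 2.3, a = 0.5, b = -0.5)
  bs <- bistability_scan(p, c(1.6, 1.8), c(2.3, 2.45), grid = c(2, 2),
                         ic_count = 6)
  expect_s3_class(bs, "bistability_map")
  cell <- bs[abs(bs$gamma - 1.6) < 1e-9 & abs(bs$omega - 2.3) < 1e-9, ]
  expect_true(cell$bistable)
  # a single initial condition degenerates to single-attractor detection
  bs1 <- bistability_scan(p, c(1.7, 1.71), c(2.3, 2.31), grid = c(2, 2),
                          ic_count = 1)
  expect_true(all(bs1$n_attractors == 1))
  expect_true(all(!bs1$bistable))
})
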