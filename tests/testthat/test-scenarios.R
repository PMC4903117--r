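test_that("the registry carries the study parameter sets", {
  sc <- get_scenario("fig7_uq_uniform")
  expect_equal(sc$params$b, -0.5)
  expect_equal(sc$params$gamma, 1)
  expect_equal(sc$params$omega1, 2)
  expect_identical(sc$sampler$distribution, "uniform")
  expect_equal(unlist(sc$sampler$args), c(lo = 0.05, hi = 0.2))
  expect_equal(sc$sampler$n, 2000)
  sc11 <- get_scenario("fig11_hysteresis")
  expect_equal(sc11$params$alpha, -1.7)
  expect_equal(sc11$params$gamma, 1.7)
  expect_equal(sc11$range, c(2.3, 2.5))
  expect_match(sc11$notes, "b=")  # the sign conflict is recorded
  sc10 <- get_scenario("fig10_pd_cascade")
  expect_equal(sc10$params$omega1, 0.5)
  expect_equal(sc10$params$beta, -0.05)
  expect_error(get_scenario("nope"), "available")
  expect_true(all(c("fig4_q1", "fig6_sweep_a", "fig12_ratio") %in%
                    list_scenarios()))
})

test_that("samplers are deterministic with the declared distributions", {
  sp <- sampler_spec("a", "point", list(v = 0.1), n = 5, seed = 1)
  expect_equal(sample_parameters(sp), rep(0.1, 5))
  su <- sampler_spec("a", "uniform", list(lo = 0.05, hi = 0.2),
                     n = 2000, seed = 7)
  x <- sample_parameters(su)
  expect_true(all(x >= 0.05 & x <= 0.2))
  expect_identical(x, sample_parameters(su))
  sn <- sampler_spec("a", "normal", list(mean = 0.125, sd = 0.025),
                     n = 4000, seed = 8)
  y <- sample_parameters(sn)
  expect_lt(abs(mean(y) - 0.125), 3 * 0.025 / sqrt(4000))
  expect_error(sampler_spec("a", "uniform", list(lo = 1, hi = 0), 10, 1),
               "lo < hi")
  expect_error(sampler_spec("a", "normal", list(mean = 0, sd = -1), 10, 1),
               "sd > 0")
})

test_that("random initial conditions are seeded, scaled and never the origin", {
  ics <- random_initial_conditions(50, 9, scale = 0.1)
  expect_length(ics, 50)
  expect_true(all(vapply(ics, function(u) any(u != 0), TRUE)))
  expect_true(all(vapply(ics, function(u) max(abs(u)) <= 0.1, TRUE)))
  expect_identical(ics, random_initial_conditions(50, 9, scale = 0.1))
  expect_false(identical(ics, random_initial_conditions(50, 10, scale = 0.1)))
  expect_length(random_initial_conditions(1, 1, dim = 2)[[1]], 2)
})

test_that("scenarios round-trip through the config format", {
  for (nm in c("fig7_uq_uniform", "fig11_hysteresis", "fig1c_blowup")) {
    sc <- get_scenario(nm)
    tf <- tempfile(fileext = ".json")
    write_scenario_config(sc, tf)
    sc2 <- read_scenario_config(tf)
    expect_identical(sc2$name, sc$name)
    expect_equal(unclass(sc2$params), unclass(sc$params))
    expect_equal(sc2$range, sc$range)
    if (!is.null(sc$sampler))
      expect_equal(unclass(sc2$sampler), unclass(sc$sampler))
  }
})
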