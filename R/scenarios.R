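# Registry of named study scenarios (fixed parameter sets from the figure
# legends of the source analyses), seeded parameter samplers and
# initial-condition generators.  Every pipeline stage is testable from
# these with no external data.

scenario_registry <- function() {
  sc <- function(name, params, free_param = NULL, range = NULL,
                 protocol, notes = "", extra = list()) {
    c(list(name = name, params = params, free_param = free_param,
           range = range, protocol = protocol, notes = notes), extra)
  }
  list(
    fig1a_single_hopf = sc(
      "fig1a_single_hopf", osc_params(1, 1, 1, 2), "gamma", c(-1, 2),
      "continuation",
      "single oscillator, supercritical Hopf at gamma = 0; omega=2, alpha=beta=1"),
    fig1c_blowup = sc(
      "fig1c_blowup", osc_params(-1, 1, 1, 2), "gamma", c(-1, 10),
      "continuation",
      "single oscillator alpha=-1, beta=1: stable branch destroyed in a heteroclinic transition near gamma=3.6586"),
    fig1d_subcritical = sc(
      "fig1d_subcritical", osc_params(1, -0.1, 0.5, 2), "gamma", c(-1, 1),
      "continuation",
      "single oscillator beta=-0.1: subcritical Hopf, fold, blow-up near gamma=-0.0226"),
    fig4_q1 = sc(
      "fig4_q1", coupled_params(1, 1, 1, 2, a = 0.5, b = 0.5), "gamma",
      c(-2, 3), "continuation",
      "first quadrant of the (a,b) plane: anti-phase only stable state; omega not printed for this figure, omega=2 adopted from the companion legends"),
    fig4_q2 = sc(
      "fig4_q2", coupled_params(1, 1, 1, 2, a = -0.5, b = 0.5), "gamma",
      c(-2, 3), "continuation", "second quadrant: phase-locked branches unstable"),
    fig4_q3 = sc(
      "fig4_q3", coupled_params(1, 1, 1, 2, a = -0.5, b = -0.5), "gamma",
      c(-2, 3), "continuation", "third quadrant: in-phase stable"),
    fig4_q4 = sc(
      "fig4_q4", coupled_params(1, 1, 1, 2, a = 0.5, b = -0.5), "gamma",
      c(-2, 3), "continuation",
      "fourth quadrant: stable phase-locked solutions born at BP_AL"),
    fig5b_twopar = sc(
      "fig5b_twopar", coupled_params(1, 1, -1, 2, a = 0.5, b = 0.5),
      "gamma", c(-2, 1), "continuation",
      "two-parameter (gamma, b) diagram at a=0.5: SN_A locus terminates on HB_A (gamma=-1) at the fold-Hopf centre b ~ 1.625"),
    fig6_sweep_a = sc(
      "fig6_sweep_a", coupled_params(1, 1, 1, 2, a = 0.1, b = -0.5), "a",
      c(-1, 1.5), "continuation",
      "continuation in a at b=-0.5, gamma=1, omega=2; legend also prints 'a=b=1', inconsistent with its own axis and body text, the self-consistent reading alpha=beta=1 is stored"),
    fig7_uq_uniform = sc(
      "fig7_uq_uniform", coupled_params(1, 1, 1, 2, a = 0.125, b = -0.5),
      "a", c(0.05, 0.2), "uq",
      "2000 seeded draws of a ~ U(0.05, 0.2); folded-lag histogram bimodal at 0 and 180 deg",
      extra = list(sampler = sampler_spec("a", "uniform",
                                          list(lo = 0.05, hi = 0.2),
                                          n = 2000, seed = 20160608))),
    fig7_uq_normal = sc(
      "fig7_uq_normal", coupled_params(1, 1, 1, 2, a = 0.125, b = -0.5),
      "a", c(0.05, 0.2), "uq",
      "normal draws of a develop a third mode near 90 deg; the mean/sd are not printed, centre 0.125 and sd 0.025 (matching the uniform support) are adopted",
      extra = list(sampler = sampler_spec("a", "normal",
                                          list(mean = 0.125, sd = 0.025),
                                          n = 2000, seed = 20160608))),
    fig8_inphase = sc(
      "fig8_inphase", coupled_params(1, 1, 5, 2, a = -0.5, b = -0.5),
      "omega", c(0.5, 4), "continuation", "in-phase branch continued in omega"),
    fig8_antiphase = sc(
      "fig8_antiphase", coupled_params(1, 1, 1.2, 2, a = 0.5, b = -0.5),
      "omega", c(0.5, 4), "continuation", "anti-phase branch continued in omega"),
    fig8_locked = sc(
      "fig8_locked", coupled_params(1, 1, 6.2, 2, a = 0.5, b = -0.5),
      "omega", c(0.5, 4), "continuation", "phase-locked branch continued in omega"),
    fig10_pd_cascade = sc(
      "fig10_pd_cascade",
      coupled_params(0.5, -0.05, 2.8, 0.5, a = 0.5, b = -0.5), "gamma",
      c(2, 3.6), "continuation",
      "period-doubling cascade for omega=0.5, alpha=0.5, beta=-0.05; chaotic regime at gamma=3.42"),
    fig11_hysteresis = sc(
      "fig11_hysteresis",
      coupled_params(-1.7, 0.5, 1.7, 2.3, a = 0.5, b = -0.5), "omega",
      c(2.3, 2.5), "sweep",
      paste("bistability of anti-phase and phase-locked states, saddle-node of the",
            "phase-locked branch near omega=2.4; the printed legend value b=0.5 is a",
            "sign typo: with b=+0.5 no bounded attractor exists off the in-phase",
            "manifold at these parameters, while b=-0.5 (the quadrant with stable",
            "phase-locked solutions) reproduces every quoted observation")),
    fig11a_bif = sc(
      "fig11a_bif", coupled_params(-1.7, 0.5, 1.7, 3, a = 0.5, b = -0.5),
      "gamma", c(-1, 4), "continuation",
      "one-parameter diagram at omega=3 (b sign as in fig11_hysteresis)"),
    fig12_ratio = sc(
      "fig12_ratio", coupled_params(1, 1, 1, 2, a = 0.5, b = -0.5),
      "ratio", c(0.7, 1.4), "continuation",
      paste("frequency-ratio continuation with omega1 fixed at 2; the source states",
            "'second quadrant' for panel (b) but phase-locked solutions are stable",
            "only in the fourth quadrant, so a=0.5, b=-0.5 is registered and the",
            "quadrant discrepancy flagged")),
    fig12c_sweep = sc(
      "fig12c_sweep", coupled_params(1, 1, 1, 2, a = 0.5, b = -0.5),
      "ratio", NULL, "sweep",
      "quasi-static sinusoidal modulation omega1(t) = omega2 (1 + sin(0.005 t))",
      extra = list(modulation = list(rate = 0.005, amplitude = 1)))
  )
}

#' Retrieve a named study scenario
#'
#' The registry holds the fixed parameter sets of the named experiments
#' (per figure), each with a provenance note, the free parameter and range
#' where applicable, the protocol kind, and attached sampler specifications
#' for the uncertainty-quantification studies.
#'
#' @param name Scenario name, e.g. `"fig7_uq_uniform"`,
#'   `"fig11_hysteresis"`, `"fig10_pd_cascade"`.  See [list_scenarios()].
#' @return A list of class `hkb_scenario` (immutable record).
#' @export
get_scenario <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  structure(reg[[name]], class = "hkb_scenario")
}

#' @rdname get_scenario
#' @export
list_scenarios <- function() names(scenario_registry())

#' @export
print.hkb_scenario <- function(x, ...) {
  cat("Scenario", x$name, "(protocol:", x$protocol, ")\n")
  print(x$params)
  if (!is.null(x$free_param))
    cat(" free:", x$free_param,
        if (!is.null(x$range)) sprintf("in [%g, %g]", x$range[1], x$range[2]),
        "\n")
  cat(" notes:", x$notes, "\n")
  invisible(x)
}

#' Sampler specification for uncertainty-quantification studies
#'
#' @param target_param Parameter to draw (e.g. `"a"`, `"ratio"`).
#' @param distribution `"uniform"`, `"normal"` or `"point"`.
#' @param args Distribution arguments: `lo`/`hi`, `mean`/`sd`, or `v`.
#' @param n Number of draws.
#' @param seed Integer seed; identical (spec, seed) give identical draws.
#' @return A list of class `sampler_spec`.
#' @export
sampler_spec <- function(target_param, distribution, args, n, seed) {
  distribution <- match.arg(distribution, c("uniform", "normal", "point"))
  if (distribution == "uniform" && !(args$lo < args$hi))
    stop("uniform sampler requires lo < hi")
  if (distribution == "normal" && !(args$sd > 0))
    stop("normal sampler requires sd > 0")
  structure(list(target_param = target_param, distribution = distribution,
                 args = args, n = n, seed = as.integer(seed)),
            class = "sampler_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Draw parameter values from a sampler specification
#'
#' @param spec A [sampler_spec()] (optionally with `n`/`seed` overridden
#'   by the arguments).
#' @param n,seed Optional overrides.
#' @return Numeric vector of length `n`; deterministic for a given seed.
#' @export
sample_parameters <- function(spec, n = spec$n, seed = spec$seed) {
  with_seed(seed, switch(spec$distribution,
    uniform = runif(n, spec$args$lo, spec$args$hi),
    normal = rnorm(n, spec$args$mean, spec$args$sd),
    point = rep(spec$args$v, n)))
}

#' Random initial conditions
#'
#' Zero-mean uniform draws on `[-scale, scale]^dim`, deterministic under
#' the seed and excluding the exact origin.
#'
#' @param n Number of states.
#' @param seed Integer seed.
#' @param scale Half-width of the sampling cube.
#' @param dim State dimension (4 for the coupled model, 2 for single).
#' @return List of numeric state vectors.
#' @export
random_initial_conditions <- function(n, seed, scale = 0.5, dim = 4) {
  stopifnot(n >= 1)
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        u <- runif(dim, -scale, scale)
        if (any(u != 0)) break
      }
      out[[i]] <- u
    }
    out
  })
}

#' Serialise a scenario to (and from) a JSON config
#'
#' @param scenario An `hkb_scenario`.
#' @param path File path.
#' @return `read_scenario_config` returns the scenario rebuilt from the
#'   file; round-trips are lossless.
#' @export
write_scenario_config <- function(scenario, path) {
  x <- unclass(scenario)
  x$params <- c(as.list(unclass(x$params)),
                list(.class = class(scenario$params)[1]))
  if (!is.null(x$sampler)) x$sampler <- unclass(x$sampler)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- x$params$.class
  pl <- x$params[setdiff(names(x$params), ".class")]
  x$params <- if (identical(pc, "coupled_params"))
    do.call(coupled_params, pl) else do.call(osc_params, pl)
  if (!is.null(x$sampler))
    x$sampler <- do.call(sampler_spec, x$sampler)
  if (!is.null(x$range)) x$range <- as.numeric(x$range)
  structure(x, class = "hkb_scenario")
}
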