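# Composite numerical experiments: uncertainty quantification of phase-lag
# distributions, quasi-static (hysteresis) sweeps, frequency-ratio studies
# and bistability-region scans.

#' Phase-lag distribution under parameter uncertainty
#'
#' Repeats seeded independent simulations with one parameter drawn from a
#' sampler, computes the post-transient relative phase of each run, and
#' histograms the lags.  Draws that diverge or fail the periodicity check
#' are counted and excluded from the histogram (never silently dropped).
#'
#' @param scenario Scenario name or `hkb_scenario` (protocol `"uq"`).
#' @param sampler Optional [sampler_spec()] overriding the scenario's.
#' @param opts List: `n` (number of draws, default from the sampler),
#'   `bin_width` (5 deg), `signed` (FALSE: fold lags to `[0, 180]`),
#'   `t_end` (280), `t_transient` (220), `ic_scale` (0.5),
#'   `min_prominence` (0.05: fraction of draws a histogram peak must rise
#'   above its neighbours to count as a mode).
#' @return A list of class `phase_lag_distribution`: `draws`, `lags`,
#'   `histogram` (`breaks`, `mids`, `counts`), `modes` (data frame of bin
#'   centre locations and counts), `n_excluded`.
#' @export
uq_phase_distribution <- function(scenario, sampler = NULL, opts = list()) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  if (is.null(sampler)) sampler <- scenario$sampler
  if (is.null(sampler)) stop("no sampler specification available")
  o <- modifyList(list(n = sampler$n, bin_width = 5, signed = FALSE,
                       t_end = 280, t_transient = 220, ic_scale = 0.5,
                       min_prominence = 0.05), opts)
  draws <- sample_parameters(sampler, n = o$n)
  ics <- random_initial_conditions(o$n, seed = sampler$seed + 1L,
                                   scale = o$ic_scale)
  lags <- rep(NA_real_, o$n)
  for (i in seq_len(o$n)) {
    pars <- set_param(scenario$params, sampler$target_param, draws[i])
    tr <- simulate(pars, ics[[i]], o$t_end,
                   opts = list(t_transient = o$t_transient))
    if (tr$meta$diverged) next
    w <- trajectory_window(tr)
    rp <- try(relative_phase(w$states[, 1], w$states[, 2], w$times),
              silent = TRUE)
    if (inherits(rp, "try-error")) next
    lags[i] <- if (o$signed) rp$lag else rp$folded
  }
  ok <- is.finite(lags)
  breaks <- if (o$signed) seq(-180, 180, by = o$bin_width)
            else seq(0, 180, by = o$bin_width)
  h <- graphics::hist(pmin(pmax(lags[ok], breaks[1]), breaks[length(breaks)]),
                      breaks = breaks, plot = FALSE)
  structure(list(draws = draws, lags = lags,
                 histogram = list(breaks = h$breaks, mids = h$mids,
                                  counts = h$counts),
                 modes = histogram_modes(h$mids, h$counts,
                                         o$min_prominence * sum(ok)),
                 n_excluded = sum(!ok), n = o$n,
                 sampler = sampler, signed = o$signed),
            class = "phase_lag_distribution")
}

# local maxima of a histogram with a prominence floor
histogram_modes <- function(mids, counts, min_prominence) {
  nb <- length(counts)
  peaks <- integer()
  for (i in seq_len(nb)) {
    left <- if (i > 1) counts[i - 1] else -Inf
    right <- if (i < nb) counts[i + 1] else -Inf
    if (counts[i] >= left && counts[i] >= right && counts[i] > 0)
      peaks <- c(peaks, i)
  }
  if (!length(peaks)) return(data.frame(location = numeric(), count = integer(),
                                        prominence = numeric()))
  prom <- vapply(peaks, function(i) {
    others <- peaks[counts[peaks] > counts[i]]
    if (!length(others)) return(counts[i] - min(counts))
    j <- others[which.min(abs(others - i))]
    valley <- min(counts[seq(min(i, j), max(i, j))])
    counts[i] - valley
  }, 0)
  keep <- prom >= min_prominence
  # merge adjacent equal-count bins into a single mode
  df <- data.frame(location = mids[peaks[keep]], count = counts[peaks[keep]],
                   prominence = prom[keep])
  df[order(-df$count), , drop = FALSE]
}

#' @export
print.phase_lag_distribution <- function(x, ...) {
  cat(sprintf("Phase-lag distribution: %d draws (%d excluded), %s lags\n",
              x$n, x$n_excluded, if (x$signed) "signed" else "folded"))
  if (nrow(x$modes)) {
    cat(" modes (bin centres):\n")
    for (i in seq_len(nrow(x$modes)))
      cat(sprintf("  %7.1f deg  (count %d)\n", x$modes$location[i],
                  x$modes$count[i]))
  }
  invisible(x)
}

#' Quasi-static parameter sweep with hysteresis detection
#'
#' Integrates the model continuously while the parameter is changed in
#' plateaus (state carried across updates, the mechanism that produces
#' hysteresis); each plateau is settled and then analysed for the relative
#' phase.  Jumps are discontinuities of the folded lag beyond
#' `jump_threshold`; the sweep is hysteretic when forward and backward
#' passes disagree beyond `hysteresis_tol` at equal parameter values.
#'
#' @param scenario Scenario name or `hkb_scenario`, or a
#'   [coupled_params()] object.
#' @param schedule Either a numeric vector of parameter values (the
#'   plateaus, e.g. up-then-down), or a list
#'   `list(param =, values =)`; if omitted, built from the scenario's
#'   range with `n_plateau` steps up then down.
#' @param opts List: `param` (swept parameter, default the scenario's free
#'   parameter), `t_settle` (100), `t_analysis` (50), `n_plateau` (40),
#'   `jump_threshold` (30 deg), `hysteresis_tol` (20 deg), `ic` (initial
#'   state; default a phase-locked-basin guess), `signed` (FALSE).
#' @return A list of class `sweep_record` with `schedule` (data frame
#'   step/value/direction), `lag_series`, `jumps`, `hysteretic`.
#' @export
quasi_static_sweep <- function(scenario, schedule = NULL, opts = list()) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  if (inherits(scenario, "hkb_scenario")) {
    params <- scenario$params
    free <- scenario$free_param
    rng <- scenario$range
  } else {
    params <- scenario; free <- NULL; rng <- NULL
  }
  o <- modifyList(list(param = free, t_settle = 100, t_analysis = 50,
                       n_plateau = 40, jump_threshold = 30,
                       hysteresis_tol = 20, ic = NULL, signed = FALSE,
                       dt = 0.01), opts)
  if (is.list(schedule) && !is.null(schedule$param)) {
    o$param <- schedule$param
    values <- schedule$values
  } else if (is.numeric(schedule)) {
    values <- schedule
  } else {
    if (is.null(rng)) stop("no schedule given and the scenario has no range")
    up <- seq(rng[1], rng[2], length.out = o$n_plateau)
    values <- c(up, rev(up)[-1])
  }
  if (is.null(o$param)) stop("swept parameter not specified")
  direction <- c(0, sign(diff(values)))
  if (is.null(o$ic)) o$ic <- c(0.4, 0.1, 0.2, -0.3)
  u <- o$ic
  lag_signed <- lag_folded <- rep(NA_real_, length(values))
  flagged <- logical(length(values))
  for (k in seq_along(values)) {
    pars <- set_param(params, o$param, values[k])
    tr <- simulate(pars, u, o$t_settle + o$t_analysis,
                   opts = list(t_transient = o$t_settle, dt = o$dt))
    if (tr$meta$diverged) { flagged[k] <- TRUE; break }
    u <- tr$states[nrow(tr$states), ]
    w <- trajectory_window(tr)
    rp <- try(relative_phase(w$states[, 1], w$states[, 2], w$times),
              silent = TRUE)
    if (inherits(rp, "try-error")) { flagged[k] <- TRUE; next }
    lag_signed[k] <- rp$lag
    lag_folded[k] <- rp$folded
  }
  lag <- if (o$signed) lag_signed else lag_folded
  # jumps between successive resolved plateaus (windows flagged as
  # aperiodic during a transition are skipped over, not treated as breaks)
  fin <- which(is.finite(lag))
  jump_from <- jump_to <- integer()
  if (length(fin) > 1) {
    dl <- abs(diff(lag[fin]))
    hit <- which(dl > o$jump_threshold)
    jump_from <- fin[hit]; jump_to <- fin[hit + 1]
  }
  jumps_df <- data.frame(step = jump_to, value_before = values[jump_from],
                         value_after = values[jump_to],
                         lag_before = lag[jump_from], lag_after = lag[jump_to])
  # forward/backward comparison at (approximately) equal parameter values
  hysteretic <- FALSE
  fwd <- which(direction >= 0); bwd <- which(direction < 0)
  for (i in fwd) {
    j <- bwd[which.min(abs(values[bwd] - values[i]))]
    if (length(j) && is.finite(lag_folded[i]) && is.finite(lag_folded[j]) &&
        abs(values[j] - values[i]) < diff(range(values)) / o$n_plateau &&
        abs(lag_folded[i] - lag_folded[j]) > o$hysteresis_tol) {
      hysteretic <- TRUE
      break
    }
  }
  structure(list(schedule = data.frame(step = seq_along(values),
                                       value = values, direction = direction),
                 lag_series = lag, lag_signed = lag_signed,
                 lag_folded = lag_folded, flagged = flagged,
                 jumps = jumps_df, hysteretic = hysteretic,
                 param = o$param),
            class = "sweep_record")
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf("Quasi-static sweep of %s: %d plateaus, %d jump(s), hysteretic: %s\n",
              x$param, nrow(x$schedule), nrow(x$jumps), x$hysteretic))
  if (nrow(x$jumps))
    for (i in seq_len(nrow(x$jumps)))
      cat(sprintf("  jump at %s ~ %.4g: lag %.1f -> %.1f deg\n", x$param,
                  x$jumps$value_after[i], x$jumps$lag_before[i],
                  x$jumps$lag_after[i]))
  invisible(x)
}

#' Continuation study in the eigenfrequency ratio
#'
#' Fixes `omega1` and continues a periodic solution of the heterogeneous
#' model in the ratio `omega1/omega2`, reporting the signed relative phase
#' along the branch and the folds where stability is lost.  Started from
#' the identical-oscillator case (`ratio = 1`), where the in-phase orbit
#' is the single-oscillator limit cycle.
#'
#' @param params A [coupled_params()] with `omega1 == omega2`.
#' @param ratio_range Continuation interval for `omega1/omega2`
#'   (containing 1).
#' @param opts Continuation options; plus `start` (`"inphase"` or an
#'   `hkb_orbit` at ratio 1) and `ntst`.
#' @return List of class `ratio_study` with `branch_up`, `branch_down`
#'   (branches toward increasing/decreasing ratio), a combined data frame
#'   `points` (ratio, lag, period, stable) and `folds`.
#' @export
frequency_ratio_study <- function(params, ratio_range = c(0.8, 1.25),
                                  opts = list()) {
  stopifnot(params$omega1 == params$omega2)
  o <- modifyList(list(start = "inphase", ntst = 50, ncol = 4,
                       ds0 = 0.01, ds_max = 0.05, max_steps = 150,
                       T_max = 200, R_max = 100), opts)
  orb0 <- o$start
  if (identical(orb0, "inphase")) {
    ps <- osc_params(params$alpha, params$beta, params$gamma, params$omega1)
    tr <- simulate(ps, c(0.1, 0), 250, opts = list(t_transient = 200))
    orb2 <- orbit_from_trajectory(tr, ps, free = "gamma",
                                  ntst = o$ntst, ncol = o$ncol)
    U4 <- rbind(orb2$profile[1, ], orb2$profile[1, ],
                orb2$profile[2, ], orb2$profile[2, ])
    model <- model_coupled()
    ctx <- make_ctx(model, params, "ratio", orb2$tau, o$ncol)
    pc <- ctx_phase_coef(ctx, U4)
    sol <- po_newton(pack_z(U4, orb2$period, 1), ctx, pc,
                     list(type = "fixed", par_value = 1))
    if (!sol$ok) stop("could not converge the ratio-1 starting orbit")
    s <- unpack_z(sol$z, ctx)
    orb0 <- new_orbit(s$U, orb2$tau, o$ncol, s$period, params, "ratio", model)
  }
  copts <- o[names(o) %in% names(default_po_opts())]
  run <- function(direction) {
    continue_periodic_branch(orb0, free = "ratio", range = ratio_range,
                             opts = c(copts, list(direction = direction)))
  }
  up <- run(1)
  dn <- run(-1)
  pts <- rbind(cbind(branch_points_df(dn)[rev(seq_len(length(dn$points))), ],
                     dir = -1),
               cbind(branch_points_df(up), dir = 1))
  folds <- c(Filter(function(b) b$kind == "SN", up$bifurcations),
             Filter(function(b) b$kind == "SN", dn$bifurcations))
  structure(list(branch_up = up, branch_down = dn, points = pts,
                 folds = folds),
            class = "ratio_study")
}

#' @export
print.ratio_study <- function(x, ...) {
  cat(sprintf("Frequency-ratio study: %d points, ratio in [%.4g, %.4g], %d fold(s)\n",
              nrow(x$points), min(x$points$par), max(x$points$par),
              length(x$folds)))
  for (f in x$folds)
    cat(sprintf("  SN at ratio = %.5g (lag %.1f deg)\n", f$par_value,
                orbit_lag(f$orbit)))
  invisible(x)
}

#' Bistability scan over a (gamma, omega) window
#'
#' Runs [enumerate_attractors()] on every cell of a parameter grid; a cell
#' is marked bistable when both an anti-phase and a phase-locked attractor
#' are found.
#'
#' @param params Base [coupled_params()].
#' @param gamma_range,omega_range Scan windows.
#' @param grid Integer `c(n_gamma, n_omega)` (each at least 2).
#' @param ic_count Initial conditions per cell.
#' @param opts List: `seed` (1), `ic_scale` (0.8), plus
#'   [enumerate_attractors()] options.
#' @return Data frame of class `bistability_map` with columns `gamma`,
#'   `omega`, `bistable`, `n_attractors`, `labels`, `status`.
#' @export
bistability_scan <- function(params, gamma_range, omega_range,
                             grid = c(3, 3), ic_count = 10, opts = list()) {
  stopifnot(all(grid >= 2) || ic_count >= 1)
  o <- modifyList(list(seed = 1L, ic_scale = 0.8), opts)
  gs <- seq(gamma_range[1], gamma_range[2], length.out = grid[1])
  ws <- seq(omega_range[1], omega_range[2], length.out = grid[2])
  rows <- list()
  cell <- 0L
  for (g in gs) for (w in ws) {
    cell <- cell + 1L
    pars <- set_param(set_param(params, "gamma", g), "omega", w)
    ics <- random_initial_conditions(ic_count, seed = o$seed + cell,
                                     scale = o$ic_scale)
    att <- try(enumerate_attractors(pars, ics,
                                    opts = o[!names(o) %in% c("seed", "ic_scale")]),
               silent = TRUE)
    if (inherits(att, "try-error")) {
      rows[[cell]] <- data.frame(gamma = g, omega = w, bistable = NA,
                                 n_attractors = NA_integer_, labels = "",
                                 status = "unknown")
      next
    }
    labs <- vapply(att, `[[`, "", "label")
    rows[[cell]] <- data.frame(
      gamma = g, omega = w,
      bistable = ("anti-phase" %in% labs) && ("phase-locked" %in% labs),
      n_attractors = length(att),
      labels = paste(unique(labs), collapse = "+"),
      status = "ok")
  }
  structure(do.call(rbind, rows), class = c("bistability_map", "data.frame"))
}
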