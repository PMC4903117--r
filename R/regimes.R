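# Relative-phase computation, coordination-regime classification,
# attractor enumeration and the largest-Lyapunov-exponent estimator.

# peak times of a sampled signal, refined by quadratic interpolation
peak_times <- function(times, x) {
  i <- which(diff(sign(diff(x))) == -2) + 1
  i <- i[i > 1 & i < length(x)]
  if (!length(i)) return(numeric())
  t0 <- times[i]
  dtm <- times[i] - times[i - 1]; dtp <- times[i + 1] - times[i]
  ym <- x[i - 1]; y0 <- x[i]; yp <- x[i + 1]
  d <- dtp * (ym - y0) - (-dtm) * (yp - y0)
  num <- dtp^2 * (ym - y0) - dtm^2 * (yp - y0)
  off <- ifelse(abs(d) > 1e-300, 0.5 * num / d, 0)
  t0 + off
}

fold_lag <- function(lag) abs(((lag + 180) %% 360) - 180)

aperiodic_error <- function(msg) {
  stop(structure(class = c("hkb_aperiodic_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Relative phase of two oscillatory signals
#'
#' Computes the lag from per-oscillator peak times: `t1`, `t2` are the
#' times at which `x1`, `x2` attain their maxima within one period, the
#' period `T` is estimated from the mean peak-to-peak spacing of `x1`, and
#' the signed lag is `360 (t2 - t1) / T` mapped to `(-180, 180]` degrees;
#' positive lag means oscillator 2 peaks later (is delayed).  The folded
#' variant `|lag|` in `[0, 180]` is returned alongside.
#'
#' @param x1,x2 Sampled position signals.
#' @param times Sample times (strictly increasing).
#' @param period_hint Optional period estimate (used only as a sanity
#'   check).
#' @param jitter_tol Maximum allowed relative standard deviation of the
#'   peak-to-peak spacing (default 1 percent); beyond it the window is
#'   declared aperiodic and an error of class `hkb_aperiodic_error` is
#'   raised.
#' @return List with `lag` (signed degrees), `folded` (degrees in
#'   `[0, 180]`) and `period`.
#' @examples
#' t <- seq(0, 40, by = 0.01)
#' relative_phase(sin(t), sin(t - 0.5), t)$lag  # about 28.6 degrees
#' @export
relative_phase <- function(x1, x2, times, period_hint = NULL,
                           jitter_tol = 0.01) {
  p1 <- peak_times(times, x1)
  p2 <- peak_times(times, x2)
  if (length(p1) < 3 || length(p2) < 2)
    aperiodic_error("too few oscillation peaks in the analysis window")
  Tper <- mean(diff(p1))
  if (stats::sd(diff(p1)) > jitter_tol * Tper)
    aperiodic_error("peak-to-peak period jitter exceeds tolerance: window aperiodic")
  if (!is.null(period_hint) && abs(Tper - period_hint) > 0.2 * period_hint)
    warning("estimated period differs from period_hint by more than 20%")
  t1 <- p1[2]
  t2c <- p2[p2 >= t1]
  if (!length(t2c)) aperiodic_error("no x2 peak found after the x1 anchor peak")
  lag <- 360 * (t2c[1] - t1) / Tper
  lag <- ((lag + 180) %% 360) - 180
  list(lag = lag, folded = fold_lag(lag), period = Tper)
}

default_regime_tols <- function() {
  list(tol_phase = 5, amp_floor = 1e-4, asym = 0.05, lyap_min = 0.01,
       check_chaos = TRUE)
}

#' Classify the coordination regime of a trajectory or orbit
#'
#' Labels: `steady` (amplitude below `amp_floor` after the transient),
#' `in-phase` (folded lag within `tol_phase` of 0), `anti-phase` (within
#' `tol_phase` of 180), `phase-locked` (in between), `chaotic` (aperiodic
#' window with positive largest Lyapunov exponent, gated at two standard
#' errors), `diverged`.  An `asymmetric-amplitude` flag is set when the
#' amplitude ratio of the two oscillators deviates from 1 by more than
#' `asym`.
#'
#' @param x An `hkb_trajectory` or `hkb_orbit`.
#' @param tols Tolerances overriding `tol_phase = 5` (deg), `amp_floor =
#'   1e-4`, `asym = 0.05`, `lyap_min = 0.01`, `check_chaos = TRUE`.
#' @return A list of class `regime_label` with `label`, `lag_degrees`
#'   (signed, periodic labels only), `folded_lag`, `amplitude_ratio`,
#'   `asymmetric`.
#' @export
classify_regime <- function(x, tols = list()) {
  tl <- modifyList(default_regime_tols(), tols)
  mk <- function(label, lag = NA_real_, ratio = NA_real_, lyap = NULL)
    structure(list(label = label, lag_degrees = lag,
                   folded_lag = if (is.na(lag)) NA_real_ else fold_lag(lag),
                   amplitude_ratio = ratio,
                   asymmetric = is.finite(ratio) && abs(ratio - 1) > tl$asym,
                   lyapunov = lyap),
              class = "regime_label")
  if (inherits(x, "hkb_orbit")) {
    U <- orbit_full_profile(x)
    if (nrow(U) == 2) return(mk("periodic"))
    ratio <- diff(range(U[1, ])) / diff(range(U[2, ]))
    lag <- profile_lag(U, x$tau, x$ncol)
    return(mk(label_from_lag(fold_lag(lag), tl), lag, ratio))
  }
  stopifnot(inherits(x, "hkb_trajectory"))
  if (x$meta$diverged) return(mk("diverged"))
  w <- trajectory_window(x)
  amp <- max(abs(w$states))
  if (amp < tl$amp_floor) return(mk("steady"))
  n <- ncol(w$states)
  if (n == 2) {
    pk <- peak_times(w$times, w$states[, 1])
    per <- length(pk) > 2 && stats::sd(diff(pk)) < 0.01 * mean(diff(pk))
    return(mk(if (per) "periodic" else "aperiodic"))
  }
  ratio <- diff(range(w$states[, 1])) / diff(range(w$states[, 2]))
  rp <- try(relative_phase(w$states[, 1], w$states[, 2], w$times),
            silent = TRUE)
  if (inherits(rp, "try-error")) {
    if (!tl$check_chaos) return(mk("aperiodic", ratio = ratio))
    ly <- try(max_lyapunov(x$params, x$states[nrow(x$states), ],
                           list(t_transient = 20)), silent = TRUE)
    if (!inherits(ly, "try-error") &&
        ly$exponent > max(tl$lyap_min, 2 * ly$se))
      return(mk("chaotic", ratio = ratio, lyap = ly))
    return(mk("aperiodic", ratio = ratio,
              lyap = if (inherits(ly, "try-error")) NULL else ly))
  }
  mk(label_from_lag(rp$folded, tl), rp$lag, ratio)
}

label_from_lag <- function(folded, tl) {
  if (folded < tl$tol_phase) "in-phase"
  else if (folded > 180 - tl$tol_phase) "anti-phase"
  else "phase-locked"
}

#' @export
print.regime_label <- function(x, ...) {
  cat("Regime:", x$label)
  if (is.finite(x$lag_degrees))
    cat(sprintf(" (lag %.1f deg, amplitude ratio %.3f%s)", x$lag_degrees,
                x$amplitude_ratio,
                if (isTRUE(x$asymmetric)) ", asymmetric" else ""))
  cat("\n")
  invisible(x)
}

#' Enumerate coexisting attractors by multistart simulation
#'
#' Simulates every initial condition, classifies the post-transient tail,
#' and merges attractors whose label, period and folded lag agree within
#' tolerances.  Phase-locked attractors found with both lag signs are
#' reported as one attractor with a `+-` lag pair.
#'
#' @param params Model parameters.
#' @param ic_set List (or matrix rows) of initial conditions.
#' @param opts List: `t_end` (default 400), `t_transient` (300),
#'   `merge_lag` (deg, 10), `merge_period` (relative, 0.05), plus
#'   [simulate()] options.
#' @return List of class `attractor_set`; each element has `label`,
#'   `lag_folded`, `lag_signs`, `period`, `basin_count`, `example_ic`.
#' @export
enumerate_attractors <- function(params, ic_set, opts = list()) {
  o <- modifyList(list(t_end = 400, t_transient = 300, merge_lag = 10,
                       merge_period = 0.05), opts)
  if (is.matrix(ic_set)) ic_set <- asplit(ic_set, 1)
  found <- list()
  for (ic in ic_set) {
    tr <- simulate(params, ic, o$t_end,
                   opts = c(list(t_transient = o$t_transient),
                            o[names(o) %in% c("dt", "rtol", "atol", "R_max")]))
    cls <- classify_regime(tr)
    Tper <- NA_real_
    if (cls$label %in% c("in-phase", "anti-phase", "phase-locked", "periodic")) {
      w <- trajectory_window(tr)
      pk <- peak_times(w$times, w$states[, 1])
      if (length(pk) > 2) Tper <- mean(diff(pk))
    }
    merged <- FALSE
    for (k in seq_along(found)) {
      f <- found[[k]]
      same <- f$label == cls$label &&
        (is.na(Tper) || is.na(f$period) ||
           abs(Tper - f$period) < o$merge_period * f$period) &&
        (is.na(cls$folded_lag) || is.na(f$lag_folded) ||
           abs(cls$folded_lag - f$lag_folded) < o$merge_lag)
      if (same) {
        f$basin_count <- f$basin_count + 1
        if (is.finite(cls$lag_degrees))
          f$lag_signs <- sort(unique(c(f$lag_signs, sign(cls$lag_degrees))))
        found[[k]] <- f
        merged <- TRUE
        break
      }
    }
    if (!merged)
      found[[length(found) + 1]] <-
        list(label = cls$label, lag_folded = cls$folded_lag,
             lag_signs = if (is.finite(cls$lag_degrees)) sign(cls$lag_degrees) else integer(),
             period = Tper, basin_count = 1L, example_ic = ic)
  }
  structure(found, class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(length(x), "distinct attractor(s):\n")
  for (f in x)
    cat(sprintf("  %-12s basin %2d%s%s\n", f$label, f$basin_count,
                if (is.finite(f$lag_folded))
                  sprintf("  lag %s%.1f deg",
                          if (length(f$lag_signs) > 1) "+-" else "", f$lag_folded)
                else "",
                if (is.finite(f$period)) sprintf("  T %.3f", f$period) else ""))
  invisible(x)
}

#' Largest Lyapunov exponent by two-trajectory renormalisation
#'
#' Benettin's method: a fiducial trajectory and a companion displaced by
#' `d0` are integrated over successive intervals of length `dt`; after
#' each interval the local expansion rate `log(d/d0)/dt` is recorded and
#' the companion is rescaled back to distance `d0` along the current
#' separation direction.  The exponent is the mean rate over `n_renorm`
#' intervals after the transient, with its standard error.
#'
#' @param params Model parameters.
#' @param ic Initial condition (must lie in the basin of a bounded
#'   attractor).
#' @param opts List: `t_transient` (200), `dt` (1), `n_renorm` (300),
#'   `d0` (1e-8), `rtol` (1e-10), `atol` (1e-12).
#' @return List with `exponent`, `se`, `rates`.
#' @export
max_lyapunov <- function(params, ic, opts = list()) {
  o <- modifyList(list(t_transient = 200, dt = 1, n_renorm = 300, d0 = 1e-8,
                       rtol = 1e-10, atol = 1e-12), opts)
  tr <- simulate(params, ic, o$t_transient,
                 opts = list(dt = o$t_transient / 50, rtol = o$rtol,
                             atol = o$atol, tolerate_blowup = FALSE,
                             t_transient = 0))
  u <- tr$states[nrow(tr$states), ]
  n <- length(u)
  dirv <- rep(1 / sqrt(n), n)
  v <- u + o$d0 * dirv
  rates <- numeric(o$n_renorm)
  step <- function(w) {
    s <- simulate(params, w, o$dt,
                  opts = list(dt = o$dt / 4, rtol = o$rtol, atol = o$atol,
                              tolerate_blowup = FALSE, t_transient = 0))
    s$states[nrow(s$states), ]
  }
  for (k in seq_len(o$n_renorm)) {
    u <- step(u); v <- step(v)
    d <- sqrt(sum((v - u)^2))
    rates[k] <- log(d / o$d0) / o$dt
    v <- u + (v - u) * (o$d0 / d)
  }
  list(exponent = mean(rates), se = stats::sd(rates) / sqrt(o$n_renorm),
       rates = rates)
}
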