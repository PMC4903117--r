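# Pseudo-arclength continuation of equilibria and periodic orbits, with
# Floquet-based stability, detection of Hopf / fold / branch-point /
# period-doubling bifurcations, branch switching and two-parameter fold
# loci.  Discretisation defaults mirror standard practice for this model
# family: NTST = 50 mesh intervals, NCOL = 4 collocation points, Newton
# tolerance 1e-9.

default_po_opts <- function() {
  list(ds0 = 0.02, ds_min = 1e-5, ds_max = 0.1, direction = 1,
       max_steps = 400, T_max = 1000, R_max = 1e3, newton_tol = 1e-9,
       adapt_mesh = FALSE, detect = TRUE, compute_floquet = TRUE,
       classify_bp = FALSE, par_stall_tol = 0, store_profiles = TRUE,
       tol_phase = 5, bisect_tol = 1e-8, max_bisect = 45, mult_cap = 1e6,
       stop_at = character(), verbose = FALSE)
}

# --- periodic-orbit object -------------------------------------------------

new_orbit <- function(U, tau, m, period, params, free, model,
                      floquet = NULL) {
  par_value <- get_param(params, free)
  structure(list(profile = U, tau = tau, ncol = m, period = period,
                 Omega = 2 * pi / period, params = params, free = free,
                 par_value = par_value, model = model, floquet = floquet,
                 stable = if (!is.null(floquet)) floquet$stable else NA),
            class = "hkb_orbit")
}

#' @export
print.hkb_orbit <- function(x, ...) {
  lag <- orbit_lag(x)
  cat(sprintf("Periodic orbit (%s): T = %.6g, Omega = %.6g, %s = %.6g%s%s\n",
              x$model$type, x$period, 2 * pi / x$period, x$free, x$par_value,
              if (!is.na(lag)) sprintf(", lag = %.2f deg", lag) else "",
              if (!is.na(x$stable)) if (x$stable) " [stable]" else " [unstable]" else ""))
  invisible(x)
}

# full-system profile (embeds manifold-reduced orbits into 4D)
orbit_full_profile <- function(orbit) {
  if (!is.null(orbit$model$embed)) orbit$model$embed(orbit$profile)
  else orbit$profile
}

orbit_lag <- function(orbit) {
  if (!is.null(orbit$model$embed))
    return(if (grepl("antiphase", orbit$model$type)) 180 else 0)
  if (orbit$model$n == 4) profile_lag(orbit$profile, orbit$tau, orbit$ncol)
  else NA_real_
}

# phase times of the two position components, as fractions of the period
orbit_phases <- function(orbit) {
  U <- orbit_full_profile(orbit)
  if (nrow(U) != 4) return(NULL)
  c(phi1 = profile_peak_time(U, orbit$tau, orbit$ncol, 1),
    phi2 = profile_peak_time(U, orbit$tau, orbit$ncol, 2))
}

# Floquet multipliers; for manifold-reduced orbits the stability is judged
# in the full 4D system along the embedded orbit.
orbit_floquet <- function(orbit, full = TRUE) {
  model <- orbit$model; U <- orbit$profile
  if (full && !is.null(model$embed)) {
    U <- model$embed(U)
    model <- model_coupled()
  }
  Mono <- po_monodromy(U, orbit$tau, orbit$ncol, orbit$period, model,
                       orbit$params)
  floquet_of(Mono)
}

orbit_regime_letter <- function(orbit, tol_phase = 5) {
  if (!is.null(orbit$model$embed))
    return(if (grepl("antiphase", orbit$model$type)) "A" else "I")
  if (orbit$model$n == 2) return("S")  # single oscillator: no phase notion
  lag <- abs(orbit_lag(orbit))
  if (lag < tol_phase) "I" else if (lag > 180 - tol_phase) "A" else "L"
}

# --- starting orbits -------------------------------------------------------

#' Small periodic orbit emanating from a Hopf bifurcation
#'
#' Builds the linear-eigenplane approximation
#' `u(t) = eps (Re q cos(2 pi t) - Im q sin(2 pi t))` at the Hopf point and
#' converges it by Newton on the collocation system, replacing the closure
#' equation by a fixed-amplitude condition so that the free parameter
#' relaxes onto the emanating branch.
#'
#' @param hb Hopf-point record: a list with `par_value`, `im` (positive
#'   imaginary part of the crossing pair) and `eigvec` (complex
#'   eigenvector), as produced by [continue_equilibrium_branch()], plus
#'   optionally `u0` (equilibrium, default origin).
#' @param params Model parameters ([osc_params()] or [coupled_params()]).
#' @param free Name of the bifurcation parameter.
#' @param eps Amplitude of the initial orbit.
#' @param ntst,ncol Collocation mesh: number of intervals and collocation
#'   points per interval.
#' @param model Internal model object; defaults to the model matching
#'   `params`.  (Used by the manifold-reduced continuation paths.)
#' @return An `hkb_orbit` object; its period is close to `2*pi/hb$im`.
#' @export
orbit_from_hopf <- function(hb, params, free, eps = 1e-3,
                            ntst = 50, ncol = 4, model = NULL) {
  if (is.null(model)) model <- model_for(params)
  n <- model$n
  if (n == 2) {
    pe <- if (!is.null(model$embed) || identical(model$type, "single")) {
      if (identical(model$type, "single")) params
      else reduced_osc(set_param(params, free, hb$par_value),
                       sub("reduced_", "", model$type))
    } else NULL
    if (!is.null(pe)) {
      s <- pe$alpha + 3 * pe$beta * pe$omega^2
      if (abs(s) < 1e-12)
        stop("degenerate Hopf bifurcation (first Lyapunov coefficient zero): cannot start a branch")
    }
  }
  params <- set_param(params, free, hb$par_value)
  q <- hb$eigvec
  q <- q / max(abs(q))
  u0 <- if (!is.null(hb$u0)) hb$u0 else numeric(n)
  tau <- seq(0, 1, length.out = ntst + 1)
  tp <- rep_point_times(tau, ncol)
  U <- sapply(tp, function(s)
    u0 + eps * (Re(q) * cos(2 * pi * s) - Im(q) * sin(2 * pi * s)))
  ctx <- make_ctx(model, params, free, tau, ncol)
  pc <- ctx_phase_coef(ctx, U)
  z0 <- pack_z(U, 2 * pi / hb$im, hb$par_value)
  sol <- po_newton(z0, ctx, pc, list(type = "amplitude", eps = eps))
  if (!sol$ok) stop("Newton failed to converge on the Hopf-emanating orbit")
  s <- unpack_z(sol$z, ctx)
  orb <- new_orbit(s$U, tau, ncol, s$period, set_param(params, free, s$par),
                   free, model)
  attr(orb, "hopf_eps") <- eps
  orb
}

#' Collocation orbit from a simulated trajectory
#'
#' Extracts one period from the tail of a (periodic) trajectory by peak
#' detection on `x1`, resamples it onto the collocation mesh and converges
#' it by Newton at fixed parameter value.
#'
#' @param traj A trajectory from [simulate()] (or any matrix-like with
#'   columns `time` then states).
#' @param params,free Model parameters and the name of the parameter that
#'   later continuation will free.
#' @param ntst,ncol Collocation mesh.
#' @return An `hkb_orbit`.
#' @export
orbit_from_trajectory <- function(traj, params, free = "gamma",
                                  ntst = 50, ncol = 4) {
  model <- model_for(params)
  out <- as.matrix(traj$raw)
  tt <- out[, 1]
  x <- out[, 2]
  use <- tt >= tt[1] + 0.5 * (tt[length(tt)] - tt[1])
  pk <- peak_times(tt[use], x[use])
  if (length(pk) < 3) stop("trajectory tail is not periodic enough to extract an orbit")
  Tper <- mean(diff(pk))
  t0 <- pk[1]
  tau <- seq(0, 1, length.out = ntst + 1)
  tp <- rep_point_times(tau, ncol)
  n <- model$n
  U <- matrix(0, n, length(tp))
  for (c in seq_len(n)) {
    f <- stats::splinefun(tt, out[, c + 1])
    U[c, ] <- f(t0 + tp * Tper)
  }
  U[, ncol(U)] <- U[, 1]
  ctx <- make_ctx(model, params, free, tau, ncol)
  pc <- ctx_phase_coef(ctx, U)
  sol <- po_newton(pack_z(U, Tper, get_param(params, free)), ctx, pc,
                   list(type = "fixed", par_value = get_param(params, free)))
  if (!sol$ok) stop("Newton failed to converge on the trajectory-derived orbit")
  s <- unpack_z(sol$z, ctx)
  new_orbit(s$U, tau, ncol, s$period, params, free, model)
}

# --- equilibrium continuation ---------------------------------------------

#' Continue an equilibrium branch with eigenvalue monitoring
#'
#' Natural-parameter continuation of `f(u; lambda) = 0` with Newton
#' correction at each step; the spectrum of the Jacobian is monitored and
#' Hopf points (a complex pair crossing the imaginary axis) are localised
#' by bisection until `|Re lambda| < 1e-8`.
#'
#' @param params Model parameters.
#' @param free Name of the free parameter.
#' @param range Numeric `c(from, to)`; the branch is swept from `from` to
#'   `to`.
#' @param u0 Starting equilibrium (default: the origin, which persists for
#'   all parameter values).
#' @param nsteps Number of sweep steps.
#' @return A list of class `hkb_eq_branch` with `points` (data frame of
#'   parameter, norm, number of unstable eigenvalues) and `bifurcations`
#'   (Hopf records usable by [orbit_from_hopf()], with a `mode` tag
#'   `"in-phase"`/`"anti-phase"` for the coupled origin).
#' @export
continue_equilibrium_branch <- function(params, free, range,
                                        u0 = NULL, nsteps = 100) {
  model <- model_for(params)
  n <- model$n
  if (is.null(u0)) u0 <- numeric(n)
  lam_seq <- seq(range[1], range[2], length.out = nsteps + 1)
  newton_eq <- function(u, pars) {
    for (it in 1:20) {
      f <- drop(model$f(matrix(u, ncol = 1), pars))
      if (max(abs(f)) < 1e-12) break
      J <- model$jac(matrix(u, ncol = 1), pars)[, , 1]
      du <- solve(J, -f)
      u <- u + du
      if (max(abs(du)) < 1e-12) break
    }
    if (max(abs(drop(model$f(matrix(u, ncol = 1), pars)))) > 1e-9)
      stop("Newton divergence on the equilibrium branch")
    u
  }
  eig_at <- function(u, pars) {
    eigen(model$jac(matrix(u, ncol = 1), pars)[, , 1])
  }
  pts <- vector("list", length(lam_seq))
  hopfs <- list()
  prev <- NULL
  u <- u0
  for (i in seq_along(lam_seq)) {
    pars <- set_param(params, free, lam_seq[i])
    u <- newton_eq(u, pars)
    e <- eig_at(u, pars)
    cplx <- abs(Im(e$values)) > 1e-10
    maxre_c <- if (any(cplx)) max(Re(e$values[cplx])) else NA_real_
    nun <- sum(Re(e$values) > 1e-12)
    pts[[i]] <- data.frame(par = lam_seq[i], norm = sqrt(sum(u^2)),
                           n_unstable = nun)
    pairs_now <- upper_pairs(e$values)
    if (!is.null(prev) && length(prev$pairs)) {
      # match pairs to the previous step by continuity, then look for a
      # sign change of the real part within each matched pair
      matched <- match_pairs(prev$pairs, pairs_now)
      for (k in seq_along(prev$pairs)) {
        cur <- matched[k]
        if (!is.finite(cur)) next
        if (sign(Re(prev$pairs[k])) != sign(Re(cur)) && Re(cur) != 0) {
          hb <- hopf_bisect(model, params, free, prev$lam, lam_seq[i],
                            u0 = u, ref_pair = prev$pairs[k],
                            newton_eq, eig_at)
          if (!is.null(hb)) hopfs[[length(hopfs) + 1]] <- hb
        }
      }
      pairs_now <- matched[is.finite(matched)]
    }
    prev <- list(lam = lam_seq[i], pairs = pairs_now)
  }
  structure(list(free = free, points = do.call(rbind, pts),
                 bifurcations = hopfs, params = params),
            class = "hkb_eq_branch")
}

# eigenvalues with positive imaginary part (one per conjugate pair)
upper_pairs <- function(ev) {
  up <- ev[Im(ev) > 1e-10]
  up[order(Im(up))]
}

# match each reference pair to the nearest current pair (greedy)
match_pairs <- function(ref, cur) {
  out <- rep(NA_complex_, length(ref))
  used <- logical(length(cur))
  for (k in seq_along(ref)) {
    if (!any(!used)) break
    idx <- which(!used)
    j <- idx[which.min(Mod(cur[idx] - ref[k]))]
    out[k] <- cur[j]
    used[j] <- TRUE
  }
  out
}

hopf_bisect <- function(model, params, free, lo, hi, u0, ref_pair,
                        newton_eq, eig_at) {
  f_re <- function(lam, ref) {
    pars <- set_param(params, free, lam)
    u <- newton_eq(u0, pars)
    e <- eig_at(u, pars)
    up <- upper_pairs(e$values)
    if (!length(up)) return(list(re = NA_real_))
    j <- which.min(Mod(up - ref))
    iv <- which.min(Mod(e$values - up[j]))
    list(re = Re(up[j]), im = Im(up[j]), pair = up[j],
         vec = e$vectors[, iv], u = u)
  }
  flo <- f_re(lo, ref_pair); fhi <- f_re(hi, ref_pair)
  if (!is.finite(flo$re) || !is.finite(fhi$re)) return(NULL)
  ref_pair <- flo$pair
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    fm <- f_re(mid, ref_pair)
    if (!is.finite(fm$re)) return(NULL)
    ref_pair <- fm$pair
    if (abs(fm$re) < 1e-9 || (hi - lo) < 1e-13) {
      mode <- NULL
      if (model$n == 4) {
        v <- fm$vec
        mode <- if (abs(v[1] - v[2]) < 1e-6 * max(abs(v))) "in-phase"
        else if (abs(v[1] + v[2]) < 1e-6 * max(abs(v))) "anti-phase" else "mixed"
      }
      return(list(kind = "HB", par_value = mid, im = abs(fm$im),
                  eigvec = fm$vec, u0 = fm$u, mode = mode,
                  test_function_residual = abs(fm$re)))
    }
    if (sign(fm$re) == sign(flo$re)) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
  }
  NULL
}

#' @export
print.hkb_eq_branch <- function(x, ...) {
  cat(sprintf("Equilibrium branch in %s over [%g, %g], %d Hopf point(s)\n",
              x$free, min(x$points$par), max(x$points$par),
              length(x$bifurcations)))
  for (hb in x$bifurcations)
    cat(sprintf("  HB at %s = %.8g (omega0 = %.6g%s)\n", x$free,
                hb$par_value, hb$im,
                if (!is.null(hb$mode)) paste0(", ", hb$mode) else ""))
  invisible(x)
}

# --- periodic-orbit continuation ------------------------------------------

#' Continue a branch of periodic orbits by pseudo-arclength
#'
#' Orthogonal-collocation continuation with adaptive step length.  At every
#' accepted solution the Floquet multipliers are computed from the
#' collocation monodromy (for orbits continued on an invariant manifold the
#' multipliers of the full four-dimensional system along the embedded orbit
#' are used), and test functions are monitored for folds (sign change of
#' the parameter component of the branch tangent, confirmed by a
#' multiplier at +1), symmetry-breaking branch points (a non-trivial
#' multiplier crossing +1 without a fold) and period doublings (a real
#' multiplier crossing -1).  Detected bifurcations are localised by
#' bisection along the branch.
#'
#' @param orbit0 Starting `hkb_orbit` (from [orbit_from_hopf()],
#'   [orbit_from_trajectory()] or [switch_branch()]).
#' @param free Free parameter name (defaults to the orbit's).
#' @param range Admissible interval for the free parameter; the branch
#'   stops when it leaves this interval.
#' @param opts Options list overriding the defaults: `ds0`, `ds_min`,
#'   `ds_max` (pseudo-arclength steps), `direction` (+1/-1 initial
#'   direction in the free parameter; ignored for Hopf starts, which step
#'   away from zero amplitude), `max_steps`, `T_max`, `R_max` (blow-up
#'   thresholds on period and amplitude), `adapt_mesh` (arclength
#'   re-meshing each step), `detect`, `compute_floquet`, `par_stall_tol`
#'   (terminate when the parameter stalls while the period grows, the
#'   blow-up signature used by [estimate_gamma_star()]).
#' @return A list of class `hkb_branch`; see [branch_points_df()] for the
#'   per-point summary and `$bifurcations` for detected points.
#' @export
continue_periodic_branch <- function(orbit0, free = orbit0$free, range,
                                     opts = list()) {
  o <- modifyList(default_po_opts(), opts)
  model <- orbit0$model
  params <- orbit0$params
  m <- orbit0$ncol
  tau <- orbit0$tau
  ctx <- make_ctx(model, params, free, tau, m)
  pc <- ctx_phase_coef(ctx, orbit0$profile)
  wz <- ctx_weights(ctx)
  z <- pack_z(orbit0$profile, orbit0$period, get_param(orbit0$params, free))
  sol <- po_newton(z, ctx, pc, list(type = "fixed", par_value = z[length(z)]),
                   tol = o$newton_tol)
  if (!sol$ok) stop("starting orbit failed to converge")
  z <- sol$z
  # initial tangent
  if (!is.null(attr(orbit0, "hopf_eps"))) {
    eps2 <- 2 * attr(orbit0, "hopf_eps")
    sol2 <- po_newton(z, ctx, pc, list(type = "amplitude", eps = eps2),
                      tol = o$newton_tol)
    if (!sol2$ok) stop("secant start from the Hopf orbit failed")
    tang <- sol2$z - z
    z <- sol2$z
    sol <- sol2
  } else if (!is.null(attr(orbit0, "tangent_hint"))) {
    tang <- attr(orbit0, "tangent_hint")
  } else {
    tang <- numeric(length(z)); tang[length(z)] <- o$direction
  }
  tang <- po_tangent(sol$J, ctx, tang, wz)
  if (is.null(tang)) stop("could not compute an initial branch tangent")

  points <- list(); bifs <- list(); status <- "max_steps"
  ds <- o$ds0
  prev <- NULL
  stall_count <- 0

  record_point <- function(z, tang, fl) {
    s <- unpack_z(z, ctx)
    orb <- new_orbit(s$U, ctx$tau, m, s$period,
                     set_param(params, free, s$par), free, model, fl)
    Ufull <- orbit_full_profile(orb)
    list(par = s$par, period = s$period, tang_par = tang[length(tang)],
         max_abs = apply(abs(Ufull), 1, max),
         lag = orbit_lag(orb),
         stable = if (!is.null(fl)) fl$stable else NA,
         floquet = if (!is.null(fl)) fl$nontrivial else NULL,
         trivial_mult = if (!is.null(fl)) fl$trivial else NA,
         orbit = if (o$store_profiles) orb else NULL)
  }
  test_funs <- function(pt) {
    mus <- pt$floquet
    # multiplier-based tests are unreliable once the monodromy is extreme
    # (near-heteroclinic orbits); suppress them there
    ok <- !is.null(mus) && all(is.finite(Mod(mus))) &&
      max(Mod(mus)) < o$mult_cap &&
      is.finite(pt$trivial_mult) && abs(pt$trivial_mult - 1) < 1e-3
    c(fold = pt$tang_par,
      plus = if (ok) Re(prod(mus - 1)) else NA_real_,
      pd   = if (ok) Re(prod(mus + 1)) else NA_real_)
  }
  converge_at <- function(z0, tang0, ds_try) {
    zp <- z0 + ds_try * tang0
    po_newton(zp, ctx, pc,
              list(type = "arclength", z0 = z0, tangent = tang0,
                   ds = ds_try, weights = wz), tol = o$newton_tol)
  }

  fl0 <- if (o$compute_floquet) {
    s0 <- unpack_z(z, ctx)
    orbit_floquet(new_orbit(s0$U, ctx$tau, m, s0$period,
                            set_param(params, free, s0$par), free, model))
  } else NULL
  prev <- record_point(z, tang, fl0)
  points[[1]] <- prev
  prev_tests <- test_funs(prev)

  for (step in seq_len(o$max_steps)) {
    sol <- converge_at(z, tang, ds)
    while (!sol$ok && ds > o$ds_min) {
      ds <- max(o$ds_min, ds / 2)
      sol <- converge_at(z, tang, ds)
    }
    if (!sol$ok) { status <- "step_underflow"; break }
    z_new <- sol$z
    tang_new <- po_tangent(sol$J, ctx, tang, wz)
    if (is.null(tang_new)) { status <- "singular_tangent"; break }
    fl <- if (o$compute_floquet) {
      s1 <- unpack_z(z_new, ctx)
      orbit_floquet(new_orbit(s1$U, ctx$tau, m, s1$period,
                              set_param(params, free, s1$par), free, model))
    } else NULL
    pt <- record_point(z_new, tang_new, fl)
    tests <- test_funs(pt)

    if (o$detect) {
      found <- detect_bifurcations(prev_tests, tests, z, tang, ds, ctx, pc,
                                   wz, o, model, params, free, m,
                                   converge_at, record_point, test_funs)
      for (bf in found) {
        dup <- any(vapply(bifs, function(b)
          b$kind == bf$kind &&
            abs(b$par_value - bf$par_value) < 1e-6 * max(1, abs(bf$par_value)) &&
            abs(b$period - bf$period) < 1e-3 * bf$period, TRUE))
        if (!dup) bifs[[length(bifs) + 1]] <- bf
      }
      if (length(bifs) &&
          any(vapply(bifs, `[[`, "", "kind") %in% o$stop_at)) {
        points[[length(points) + 1]] <- pt
        status <- "stopped_at_bifurcation"
        break
      }
    }
    points[[length(points) + 1]] <- pt
    # termination checks
    if (pt$period > o$T_max) { status <- "T_max"; z <- z_new; break }
    if (max(pt$max_abs) > o$R_max) { status <- "R_max"; z <- z_new; break }
    if (pt$par < min(range) || pt$par > max(range)) { status <- "range"; z <- z_new; break }
    if (o$par_stall_tol > 0) {
      if (abs(pt$par - prev$par) < o$par_stall_tol &&
          pt$period > prev$period) stall_count <- stall_count + 1
      else stall_count <- 0
      if (stall_count >= 5) { status <- "par_stall"; z <- z_new; break }
    }
    # step-size control on Newton effort
    if (sol$iter <= 3) ds <- min(o$ds_max, ds * 1.4)
    else if (sol$iter >= 6) ds <- max(o$ds_min, ds / 1.5)
    z <- z_new; tang <- tang_new; prev <- pt; prev_tests <- tests
    # mesh adaptation for the next step
    if (o$adapt_mesh) {
      s1 <- unpack_z(z, ctx)
      rm <- remesh_orbit(s1$U, ctx$tau, m)
      if (!identical(rm$tau, ctx$tau)) {
        ctx2 <- make_ctx(model, params, free, rm$tau, m)
        pc2 <- ctx_phase_coef(ctx2, rm$U)
        z2 <- pack_z(rm$U, s1$period, s1$par)
        sol2 <- po_newton(z2, ctx2, pc2,
                          list(type = "fixed", par_value = s1$par),
                          tol = o$newton_tol)
        if (sol2$ok) {
          tang_prof <- matrix(tang[seq_len(ctx$n * (ctx$M + 1))],
                              ctx$n, ctx$M + 1)
          tang_prof <- profile_eval(tang_prof, ctx$tau, m,
                                    rep_point_times(rm$tau, m))
          ctx <- ctx2
          z <- sol2$z
          tang <- c(as.vector(tang_prof), tail(tang, 2))
          wz <- ctx_weights(ctx)
          tang <- tang / sqrt(sum(wz * tang^2))
          pc <- pc2
        }
      }
    }
    # refresh the phase reference
    s1 <- unpack_z(z, ctx)
    pc <- ctx_phase_coef(ctx, s1$U)
  }
  structure(list(free = free, points = points, bifurcations = bifs,
                 status = status, params = params,
                 provenance = list(model = model$type, ntst = length(orbit0$tau) - 1,
                                   ncol = m)),
            class = "hkb_branch")
}

# bisection localisation of sign changes of the test functions between the
# last two accepted solutions
detect_bifurcations <- function(tests0, tests1, z0, tang0, ds, ctx, pc, wz,
                                o, model, params, free, m,
                                converge_at, record_point, test_funs) {
  out <- list()
  sgn_change <- function(a, b) is.finite(a) && is.finite(b) && a * b < 0
  want <- c(
    fold = sgn_change(tests0["fold"], tests1["fold"]),
    plus = sgn_change(tests0["plus"], tests1["plus"]),
    pd   = sgn_change(tests0["pd"], tests1["pd"]))
  if (!any(want)) return(out)
  eval_frac <- function(fr) {
    sol <- converge_at(z0, tang0, fr * ds)
    if (!sol$ok) return(NULL)
    tg <- po_tangent(sol$J, ctx, tang0, wz)
    s <- unpack_z(sol$z, ctx)
    fl <- orbit_floquet(new_orbit(s$U, ctx$tau, m, s$period,
                                  set_param(params, free, s$par), free, model))
    pt <- record_point(sol$z, tg, fl)
    list(pt = pt, tests = test_funs(pt))
  }
  for (which_t in names(want)[want]) {
    lo <- 0; hi <- 1
    tlo <- tests0[which_t]; thi <- tests1[which_t]
    best <- NULL
    for (it in seq_len(o$max_bisect)) {
      mid <- (lo + hi) / 2
      em <- eval_frac(mid)
      if (is.null(em)) break
      tm <- em$tests[which_t]
      best <- em
      if (!is.finite(tm)) break
      if (abs(tm) < o$bisect_tol || (hi - lo) * ds < 1e-10) break
      if (sign(tm) == sign(tlo)) { lo <- mid; tlo <- tm } else { hi <- mid; thi <- tm }
    }
    if (is.null(best)) next
    pt <- best$pt
    kind <- switch(which_t,
      fold = "SN",
      plus = if (want["fold"]) "SN" else "BP",
      pd = "PD")
    if (which_t == "plus" && want["fold"]) next  # already recorded as SN via fold
    reg <- orbit_regime_letter(pt$orbit, o$tol_phase)
    label <- paste0(kind, "_", reg)
    if (kind == "PD") label <- paste0(label, reg)
    if (kind == "BP" && isTRUE(o$classify_bp)) {
      # classify the bifurcating family by switching onto it and following
      # it a short way (the lag leaves the symmetric value continuously)
      sw <- try(switch_branch(list(kind = kind, orbit = pt$orbit), eps = 1e-2),
                silent = TRUE)
      if (!inherits(sw, "try-error")) {
        bsw <- try(continue_periodic_branch(
          sw, free = free, range = pt$par + c(-2, 2),
          opts = list(max_steps = 15, ds0 = 0.03, ds_max = 0.1,
                      detect = FALSE, compute_floquet = FALSE)),
          silent = TRUE)
        last <- if (!inherits(bsw, "try-error"))
          bsw$points[[length(bsw$points)]]$orbit else sw
        label <- paste0(label, orbit_regime_letter(last, o$tol_phase))
      }
    } else if (kind == "BP") {
      label <- paste0(label, "?")
    }
    out[[length(out) + 1]] <-
      list(kind = kind, label = label, par_value = pt$par,
           period = pt$period, orbit = pt$orbit,
           test_function_residual = unname(best$tests[which_t]))
  }
  out
}

#' Per-point summary of a periodic-orbit branch
#'
#' @param branch An `hkb_branch` from [continue_periodic_branch()].
#' @return A data frame with the free-parameter value, period, angular
#'   frequency, per-component amplitude maxima, relative phase (degrees,
#'   coupled orbits) and stability of every accepted point.
#' @export
branch_points_df <- function(branch) {
  pts <- branch$points
  namp <- length(pts[[1]]$max_abs)
  df <- data.frame(
    par = vapply(pts, `[[`, 0, "par"),
    period = vapply(pts, `[[`, 0, "period"))
  df$Omega <- 2 * pi / df$period
  for (i in seq_len(namp))
    df[[paste0("max_abs_", i)]] <- vapply(pts, function(p) p$max_abs[i], 0)
  df$lag <- vapply(pts, function(p) if (is.null(p$lag)) NA_real_ else p$lag, 0)
  df$stable <- vapply(pts, function(p) isTRUE(p$stable), NA)
  df
}

#' @export
print.hkb_branch <- function(x, ...) {
  df <- branch_points_df(x)
  cat(sprintf("Periodic-orbit branch in %s: %d points, %s in [%.5g, %.5g], status %s\n",
              x$free, nrow(df), x$free, min(df$par), max(df$par), x$status))
  for (bf in x$bifurcations)
    cat(sprintf("  %s at %s = %.8g (T = %.5g)\n", bf$label, x$free,
                bf$par_value, bf$period))
  invisible(x)
}

# --- branch switching ------------------------------------------------------

#' Switch to a bifurcating branch at a branch point or period doubling
#'
#' At a symmetry-breaking branch point the critical Floquet eigenfunction
#' (multiplier +1, least aligned with the phase direction) is propagated
#' along the orbit via the collocation transfer matrices and used to
#' perturb the critical solution, which is then re-converged by Newton at a
#' parameter value slightly off the bifurcation; the converged solution
#' lies on the bifurcating (lower-symmetry) branch.  At a period doubling
#' the mesh is doubled and the perturbation is applied antiperiodically.
#'
#' @param bp A bifurcation record from a branch (`$bifurcations[[i]]`), or
#'   a list with fields `kind` (`"BP"` or `"PD"`) and `orbit`.
#' @param eps Relative perturbation amplitude.
#' @param dpar Parameter offsets to try (both signs are attempted).
#' @return An `hkb_orbit` on the bifurcating branch (in the full system if
#'   the source orbit lived on an invariant manifold), carrying a tangent
#'   hint so that [continue_periodic_branch()] can extend it.
#' @export
switch_branch <- function(bp, eps = 1e-2, dpar = c(1e-3, 5e-3, 2e-2)) {
  orbit <- bp$orbit
  free <- orbit$free
  # work in the full system
  if (!is.null(orbit$model$embed)) {
    U <- orbit$model$embed(orbit$profile)
    model <- model_coupled()
    orbit <- new_orbit(U, orbit$tau, orbit$ncol, orbit$period, orbit$params,
                       free, model)
  }
  model <- orbit$model
  params <- orbit$params
  m <- orbit$ncol; tau <- orbit$tau
  U <- orbit$profile; Tper <- orbit$period
  Mono <- po_monodromy(U, tau, m, Tper, model, params)
  e <- eigen(Mono)
  target <- if (bp$kind == "PD") -1 else 1
  cand <- order(Mod(e$values - target))
  f0 <- drop(model$f(U[, 1, drop = FALSE], params))
  f0 <- f0 / sqrt(sum(f0^2))
  pick <- NULL
  for (i in cand[1:min(3, length(cand))]) {
    v <- e$vectors[, i]
    if (max(abs(Im(v))) < 1e-6 * max(abs(v))) v <- Re(v) else next
    v <- v / sqrt(sum(v^2))
    if (bp$kind == "PD" || abs(sum(v * f0)) < 0.9) { pick <- v; break }
  }
  if (is.null(pick)) stop("no real critical eigenvector found at the bifurcation point")
  W <- po_propagate(U, tau, m, Tper, model, params, pick)
  W <- W / max(abs(W))
  scale <- max(abs(U))
  lam0 <- get_param(params, free)
  attempts <- character()
  if (bp$kind == "PD") {
    tau_sw <- c(tau / 2, 0.5 + tau[-1] / 2)
    U_sw <- cbind(U, U[, -1, drop = FALSE])
    W_sw <- cbind(W, -W[, -1, drop = FALSE])
    T_sw <- 2 * Tper
  } else {
    tau_sw <- tau; U_sw <- U; W_sw <- W; T_sw <- Tper
  }
  # free the parameter and instead pin the projection of the deviation onto
  # the critical eigenfunction: at a pitchfork (or doubling) this forces
  # Newton onto the bifurcating branch while the parameter relaxes to the
  # side where it exists
  ctx <- make_ctx(model, params, free, tau_sw, m)
  wz <- ctx_weights(ctx)
  proj <- c(as.vector(W_sw), 0, 0)
  proj <- proj / sqrt(sum(wz * proj^2))
  z_bif <- pack_z(U_sw, T_sw, lam0)
  for (amp in eps * c(1, 3, 0.3)) {
    for (s in c(1, -1)) {
      ds <- s * amp * scale
      Ut <- U_sw + ds * matrix(proj[seq_len(length(W_sw))], nrow(W_sw))
      pc <- ctx_phase_coef(ctx, U_sw)
      sol <- po_newton(z_bif + ds * proj, ctx, pc,
                       list(type = "arclength", z0 = z_bif, tangent = proj,
                            ds = ds, weights = wz))
      if (sol$ok) {
        sN <- unpack_z(sol$z, ctx)
        dist <- max(abs(sN$U - U_sw))
        genuine <- if (bp$kind == "PD") {
          half <- profile_eval(sN$U, tau_sw, m,
                               (rep_point_times(tau_sw, m) + 0.5) %% 1)
          max(abs(half - sN$U)) > 0.1 * dist && dist > 1e-8 * scale
        } else dist > 1e-8 * scale
        if (genuine) {
          pars <- set_param(params, free, sN$par)
          orb <- new_orbit(sN$U, tau_sw, m, sN$period, pars, free, model)
          attr(orb, "tangent_hint") <- sol$z - z_bif
          return(orb)
        }
      }
      attempts <- c(attempts, sprintf("amp=%g s=%d ok=%s", amp, s, sol$ok))
    }
  }
  stop("branch switching failed on both sides; attempts: ",
       paste(attempts, collapse = "; "))
}

# propagate an initial deviation through the linearised collocation system
po_propagate <- function(U, tau, m, period, model, pars, v) {
  n <- model$n; N <- length(tau) - 1
  g <- gauss_legendre(m)
  lm <- lagrange_matrices((0:m) / m, g$z)
  h <- diff(tau)
  W <- matrix(0, n, N * m + 1)
  W[, 1] <- v
  for (j in seq_len(N)) {
    cols <- ((j - 1) * m + 1):((j - 1) * m + m + 1)
    Ub <- U[, cols, drop = FALSE]
    Ug <- Ub %*% t(lm$L)
    Ag <- model$jac(Ug, pars)
    E <- matrix(0, m * n, (m + 1) * n)
    for (i in seq_len(m)) {
      ri <- (i - 1) * n + seq_len(n)
      Ai <- Ag[, , i]
      for (k in seq_len(m + 1)) {
        ci <- (k - 1) * n + seq_len(n)
        blk <- -period * lm$L[i, k] * Ai
        diag(blk) <- diag(blk) + lm$D[i, k] / h[j]
        E[ri, ci] <- blk
      }
    }
    B <- E[, n + seq_len(m * n), drop = FALSE]
    C <- E[, seq_len(n), drop = FALSE]
    X <- solve(B, -C %*% W[, cols[1]])
    W[, cols[-1]] <- matrix(X, n, m)
  }
  W
}

#' Continue the in-phase or anti-phase branch of the coupled model
#'
#' In-phase and anti-phase periodic solutions of the identical-oscillator
#' model live on invariant manifolds (`x2 = x1` and `x2 = -x1`) on which
#' the dynamics reduce exactly to a single HKB oscillator (with
#' `alpha - 8b` and `gamma + 2a` replacing `alpha` and `gamma` in the
#' anti-phase case).  The branch is therefore continued in the reduced
#' planar system, starting from the corresponding Hopf bifurcation of the
#' trivial state (`gamma = 0` for in-phase, `gamma = -2a` for anti-phase),
#' while stability and symmetry-breaking bifurcations are judged from the
#' Floquet multipliers of the full four-dimensional system along the
#' embedded orbit.
#'
#' @param params A [coupled_params()] with `omega1 == omega2`.
#' @param mode `"antiphase"` or `"inphase"`.
#' @param free Free parameter (`"gamma"`, `"a"`, `"b"`, `"omega"`, ...).
#' @param range Continuation interval.
#' @param opts Options for [continue_periodic_branch()].
#' @param eps Starting orbit amplitude.
#' @return An `hkb_branch`.
#' @export
coupled_mode_branch <- function(params, mode = c("antiphase", "inphase"),
                                free = "gamma", range, opts = list(),
                                eps = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(params$omega1 == params$omega2)
  model <- model_reduced(mode)
  gH <- if (mode == "antiphase") -2 * params$a else 0
  pars <- params
  if (free == "gamma") {
    pars <- set_param(pars, "gamma", gH)
  } else if (abs(reduced_osc(pars, mode)$gamma) > 1e-12) {
    stop("for free parameters other than gamma, `params` must sit on the ",
         mode, " Hopf locus (gamma = ", gH, ")")
  }
  w <- pars$omega1
  orb <- orbit_from_hopf(list(par_value = get_param(pars, free), im = w,
                              eigvec = c(1, 1i * w)),
                         params = pars, free = free, eps = eps,
                         ntst = if (is.null(opts$ntst)) 50 else opts$ntst,
                         ncol = if (is.null(opts$ncol)) 4 else opts$ncol,
                         model = model)
  continue_periodic_branch(orb, free = free, range = range, opts = opts)
}

# --- two-parameter fold loci and the fold-Hopf point -----------------------

#' Locus of saddle-node bifurcations in two parameters
#'
#' For each value of the second parameter, re-runs a one-parameter
#' continuation in the first parameter (started from the Hopf point of the
#' anti-phase mode for anti-phase branches, or from a supplied seed orbit)
#' and records the location of the first fold.  The locus is truncated
#' with an end event when the fold disappears.
#'
#' @param params Base [coupled_params()].
#' @param p1 Name of the continuation parameter (the fold coordinate).
#' @param p2 Name of the grid parameter.
#' @param p2_values Grid of values for `p2`.
#' @param manifold `"antiphase"` to continue the (manifold-reduced)
#'   anti-phase branch, the standard use here.
#' @param opts Continuation options (see [continue_periodic_branch()]).
#' @return Data frame with columns `p2`, `p1_sn` (`NA` past the end event)
#'   and attribute `end_event`.
#' @export
fold_locus_two_param <- function(params, p1 = "gamma", p2 = "b", p2_values,
                                 manifold = "antiphase", opts = list()) {
  rows <- lapply(p2_values, function(v) {
    pars <- set_param(params, p2, v)
    sn <- antiphase_fold(pars, free = p1, opts = opts)
    data.frame(p2 = v, p1_sn = if (is.null(sn)) NA_real_ else sn$par_value)
  })
  out <- do.call(rbind, rows)
  attr(out, "end_event") <- if (anyNA(out$p1_sn))
    sprintf("fold not detected for %s = %s", p2,
            paste(out$p2[is.na(out$p1_sn)], collapse = ", "))
  else "none"
  out
}

# first fold of the anti-phase branch emanating from its Hopf point,
# continued in the reduced planar system
antiphase_fold <- function(params, free = "gamma", opts = list()) {
  model <- model_reduced("antiphase")
  gH <- -2 * params$a
  pars <- set_param(params, "gamma", gH)
  w <- pars$omega1
  orb <- try(orbit_from_hopf(list(par_value = get_param(pars, free), im = w,
                                  eigvec = c(1, 1i * w)),
                             params = pars, free = free, eps = 1e-3,
                             ntst = 50, ncol = 4, model = model),
             silent = TRUE)
  if (inherits(orb, "try-error")) return(NULL)
  o <- modifyList(list(ds0 = 5e-3, ds_max = 0.05, max_steps = 250,
                       compute_floquet = FALSE, detect = TRUE,
                       classify_bp = FALSE, T_max = 100, R_max = 200,
                       adapt_mesh = TRUE, par_stall_tol = 1e-9,
                       stop_at = "SN"),
                  opts)
  rng <- get_param(pars, free) + c(-2, 2)
  br <- try(continue_periodic_branch(orb, free = free, range = rng, opts = o),
            silent = TRUE)
  if (inherits(br, "try-error")) return(NULL)
  sns <- Filter(function(b) b$kind == "SN", br$bifurcations)
  if (!length(sns)) return(NULL)
  sns[[1]]  # first fold along the branch
}

#' Locate the fold-Hopf organising centre in the (gamma, b) plane
#'
#' The saddle-node locus of anti-phase periodic orbits terminates on the
#' anti-phase Hopf line `gamma = -2a` of the trivial state.  This routine
#' locates the termination point by bisection in `b`: for each trial `b`
#' the anti-phase branch is continued in `gamma` from its Hopf point and
#' the fold `SN_A` is located (it exists on the subcritical side); the
#' bisection tightens until the fold's gamma-coordinate coincides with the
#' Hopf gamma to `gamma_tol`, or the `b` bracket is below `b_tol`.
#'
#' @param a Velocity coupling.
#' @param omega Common eigenfrequency.
#' @param alpha,beta Intrinsic nonlinearity parameters.
#' @param b_window Search window for `b`.
#' @param gamma_tol,b_tol Convergence tolerances.
#' @return List with `gamma_FH` (gamma of the last located fold, which
#'   converges onto the Hopf line), `b_FH`, `gamma_hopf = -2a`, and the
#'   bisection `history`.
#' @export
find_fold_hopf <- function(a, omega, alpha = 1, beta = 1,
                           b_window = c(0.5, 2.5), gamma_tol = 1e-4,
                           b_tol = 2e-3) {
  base <- coupled_params(alpha, beta, gamma = -2 * a, omega = omega,
                         a = a, b = 0)
  gH <- -2 * a
  probe <- function(b) {
    sn <- antiphase_fold(set_param(base, "b", b))
    if (is.null(sn)) NA_real_ else sn$par_value
  }
  hist <- list()
  note <- function(b, g) hist[[length(hist) + 1]] <<- data.frame(b = b, gamma_sn = g)
  # coarse scan for a sign change of gamma_SN(b) - gamma_H
  bs <- seq(b_window[1], b_window[2], length.out = 6)
  gs <- vapply(bs, probe, 0)
  for (i in seq_along(bs)) note(bs[i], gs[i])
  h <- gs - gH
  idx <- which(is.finite(h[-length(h)]) & is.finite(h[-1]) &
                 h[-length(h)] * h[-1] < 0)
  if (!length(idx))
    stop("SN_A locus does not cross the anti-phase Hopf line in the scanned ",
         "b window [", b_window[1], ", ", b_window[2], "]")
  b_lo <- bs[idx[1]]; h_lo <- h[idx[1]]
  b_hi <- bs[idx[1] + 1]
  g_best <- gs[idx[1]]; b_best <- b_lo
  while ((b_hi - b_lo) > b_tol && abs(g_best - gH) > gamma_tol) {
    bm <- (b_lo + b_hi) / 2
    g <- probe(bm)
    note(bm, g)
    if (!is.finite(g)) break
    if (abs(g - gH) < abs(g_best - gH)) { g_best <- g; b_best <- bm }
    if ((g - gH) * h_lo > 0) { b_lo <- bm; h_lo <- g - gH } else b_hi <- bm
  }
  list(gamma_FH = g_best, b_FH = (b_lo + b_hi) / 2, gamma_hopf = gH,
       history = do.call(rbind, hist))
}
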