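#' Poincare-sphere projection of the plane
#'
#' Maps a finite point `(x, y)` to the upper hemisphere through
#' `X = x/N, Y = y/N, Z = 1/N` with `N = sqrt(1 + x^2 + y^2)`, a bijection
#' between the plane and `Z > 0`; the equator `Z = 0` represents infinity.
#'
#' @param x,y Finite plane coordinates.
#' @return Named numeric vector `c(X, Y, Z)` on the unit sphere.
#' @examples
#' sphere_project(1, 0)
#' @export
sphere_project <- function(x, y) {
  if (!is.finite(x) || !is.finite(y)) blowup_error(c(x, y))
  n <- sqrt(1 + x^2 + y^2)
  c(X = x / n, Y = y / n, Z = 1 / n)
}

#' @rdname sphere_project
#' @param s Sphere point `c(X, Y, Z)` with `Z > 0`.
#' @export
sphere_unproject <- function(s) {
  if (s[["Z"]] <= 0)
    stop(structure(class = c("hkb_infinity_error", "error", "condition"),
                   list(message = "point at infinity (Z <= 0) has no finite preimage",
                        call = sys.call())))
  c(x = s[["X"]] / s[["Z"]], y = s[["Y"]] / s[["Z"]])
}

#' Compactified HKB vector field on the Poincare sphere
#'
#' Pushforward of the single-oscillator field under [sphere_project()].
#' Near the equator the raw pushforward carries a `1/Z^2` singularity; the
#' desingularised variant multiplies the field by `Z^2`, a positive time
#' rescaling on `Z > 0` that extends smoothly to the equator and preserves
#' orbits, which is what classification of the equilibria at infinity
#' requires.
#'
#' @param s Sphere point `c(X, Y, Z)`.
#' @param params An [osc_params()] object.
#' @param desingularized If `TRUE` return the polynomial field `Z^2 *`
#'   (pushforward), defined on the whole closed hemisphere.
#' @return Tangent vector `c(X., Y., Z.)` with `X*X. + Y*Y. + Z*Z. = 0`.
#' @export
compactified_rhs <- function(s, params, desingularized = FALSE) {
  X <- s[[1]]; Y <- s[[2]]; Z <- s[[3]]
  if (!desingularized) {
    if (Z == 0)
      stop(structure(class = c("hkb_infinity_error", "error", "condition"),
                     list(message = "Z == 0 requires desingularized = TRUE",
                          call = sys.call())))
    u <- c(X / Z, Y / Z)
    f <- hkb_rhs(u, params)
    r <- X * f[1] + Y * f[2]
    return(c(X. = Z * (f[1] - X * r), Y. = Z * (f[2] - Y * r),
             Z. = -Z^2 * r))
  }
  # polynomial form: Z^3 * P = Y Z^2 ;  Z^3 * Q as below
  p3 <- Y * Z^2
  q3 <- -Y * (params$alpha * X^2 + params$beta * Y^2) +
    params$gamma * Y * Z^2 - params$omega^2 * X * Z^2
  c(X. = (1 - X^2) * p3 - X * Y * q3,
    Y. = -X * Y * p3 + (1 - Y^2) * q3,
    Z. = -Z * (X * p3 + Y * q3))
}

#' Flow on the equator of the Poincare sphere
#'
#' The equator flow of the compactified single oscillator is governed by
#' `G4(theta) = cos(theta) Q3 - sin(theta) P3` evaluated on the unit
#' circle, where `P3 = 0` and `Q3 = -alpha x^2 y - beta y^3` are the cubic
#' parts of the vector field.  `G4 > 0` means counterclockwise flow,
#' `G4 < 0` clockwise; its roots are the equilibria at infinity.
#'
#' @param theta Angle(s) along the equator, radians.
#' @param alpha,beta Nonlinearity coefficients.
#' @return `G4(theta)`, vectorised over `theta`.
#' @examples
#' equator_flow(pi / 4, 1, 1)  # -0.5: clockwise
#' @export
equator_flow <- function(theta, alpha, beta) {
  ct <- cos(theta); st <- sin(theta)
  -ct * st * (alpha * ct^2 + beta * st^2)
}

#' Equilibria at infinity of the single HKB oscillator
#'
#' Solves `G4(theta) = -cos(theta) sin(theta) (alpha cos^2 + beta sin^2) = 0`
#' on the unit circle.  The axis points `(0, +-1)` and `(+-1, 0)` are always
#' equilibria; four additional diagonal equilibria with
#' `alpha X^2 + beta Y^2 = 0` exist exactly when `alpha` and `beta` have
#' opposite signs, for a total of eight.
#'
#' @param alpha,beta Nonlinearity coefficients, not both zero.
#' @return A list of class `equator_equilibria`; each element has fields
#'   `theta`, `X`, `Y`, `hyperbolic`, and the signs of the equator flow on
#'   either side (`flow_sign_left`, `flow_sign_right`).
#' @examples
#' length(equator_equilibria(-1, 1))  # 8
#' length(equator_equilibria(1, 1))   # 4
#' @export
equator_equilibria <- function(alpha, beta) {
  if (alpha == 0 && beta == 0)
    stop("degenerate field: alpha and beta cannot both be zero")
  thetas <- c(0, pi / 2, pi, 3 * pi / 2)
  if (alpha * beta < 0) {
    t0 <- atan(sqrt(-alpha / beta))   # in (0, pi/2)
    thetas <- c(thetas, t0, pi - t0, pi + t0, 2 * pi - t0)
  }
  thetas <- sort(thetas %% (2 * pi))
  eps <- 1e-4
  out <- lapply(thetas, function(th) {
    structure(list(
      theta = th, X = cos(th), Y = sin(th),
      hyperbolic = abs(cos(th)) < 1e-12,  # only (0, +-1) are hyperbolic
      flow_sign_left = sign(equator_flow(th - eps, alpha, beta)),
      flow_sign_right = sign(equator_flow(th + eps, alpha, beta)),
      local_type = NULL), class = "equator_equilibrium")
  })
  structure(out, class = "equator_equilibria", alpha = alpha, beta = beta)
}

#' @export
print.equator_equilibria <- function(x, ...) {
  cat(sprintf("%d equilibria at infinity (alpha=%g, beta=%g):\n",
              length(x), attr(x, "alpha"), attr(x, "beta")))
  for (e in x)
    cat(sprintf("  theta=%8.5f  (X, Y)=(% .4f, % .4f)%s\n",
                e$theta, e$X, e$Y,
                if (e$hyperbolic) "  [hyperbolic]" else ""))
  invisible(x)
}

#' Classify an equilibrium at infinity
#'
#' The hyperbolic pair `(0, +-1)` is classified analytically: stable nodes
#' for `beta < 0`, unstable nodes for `beta > 0`.  The remaining equilibria
#' are non-hyperbolic and are classified numerically, by combining the
#' equator flow direction on either side with short integrations of the
#' desingularised flow started just inside the hemisphere: counting how
#' many of the three local directions (two along the equator, one interior)
#' are attracting yields `stable node` (all), `unstable node` (none) or
#' `saddle` (mixed); an inconclusive interior test yields `undetermined`.
#'
#' @param e One element of [equator_equilibria()].
#' @param params An [osc_params()] object supplying `gamma` and `omega`
#'   (the cubic part only fixes `alpha`, `beta`).
#' @param z0 Starting height of the interior probe trajectory.
#' @param t_probe Integration time of the probe (desingularised time).
#' @return One of `"stable node"`, `"unstable node"`, `"saddle"`,
#'   `"undetermined"`.
#' @export
classify_equator_equilibrium <- function(e, params, z0 = 0.02, t_probe = 20) {
  if (e$hyperbolic) {
    if (params$beta < 0) return("stable node")
    if (params$beta > 0) return("unstable node")
    return("undetermined")
  }
  # equator directions: does the equator flow point toward the equilibrium?
  # left side (theta - eps): toward iff counterclockwise (G4 > 0)
  n_toward <- sum(c(e$flow_sign_left > 0, e$flow_sign_right < 0))
  if (n_toward == 1) return("saddle")
  # interior probe just inside the hemisphere above (X, Y); forward time for
  # a candidate stable node, backward time for a candidate unstable node
  s0 <- c(e$X * sqrt(1 - z0^2), e$Y * sqrt(1 - z0^2), z0)
  f <- function(t, s, p)
    list(sign(t_dir) * compactified_rhs(s, params, desingularized = TRUE))
  dist0 <- sqrt(sum((s0 - c(e$X, e$Y, 0))^2))
  probe <- function(tt, dir) {
    t_dir <<- dir
    out <- try(suppressWarnings(
      deSolve::ode(s0, c(0, tt), f, NULL, rtol = 1e-10, atol = 1e-12,
                   maxsteps = 50000)), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < 2 ||
        !all(is.finite(out[nrow(out), 2:4]))) return(NA)
    s1 <- out[nrow(out), 2:4]
    sqrt(sum((s1 - c(e$X, e$Y, 0))^2)) / dist0
  }
  t_dir <- 1
  dir <- if (n_toward == 2) 1 else -1
  appr <- fail <- FALSE
  for (tt in t_probe * c(1, 10, 100)) {
    r <- probe(tt, dir)
    if (is.na(r)) { fail <- TRUE; next }
    fail <- FALSE
    if (r < 0.8) { appr <- TRUE; break }
    if (r > 3) break   # clearly departing
  }
  if (fail) return("undetermined")
  if (n_toward == 2) {
    if (appr) "stable node" else "saddle"
  } else {
    if (appr) "unstable node" else "saddle"
  }
}

#' Estimate the critical damping of the heteroclinic transition
#'
#' When `alpha` and `beta` have opposite signs the stable limit cycle of
#' the single HKB oscillator grows with `gamma` and is destroyed at a
#' critical `gamma*` where it becomes a heteroclinic cycle through four
#' saddle equilibria at infinity; its period diverges logarithmically,
#' `T(gamma) = A - B log(gamma* - gamma)`.  This routine continues the
#' stable periodic branch in `gamma` (through the fold first, if the Hopf
#' is subcritical), detects the blow-up signature (period or amplitude
#' exceeding thresholds, or stalling of the continuation parameter), and
#' recovers `gamma*` as the asymptote of the logarithmic period law fitted
#' on the branch tail.
#'
#' @param alpha,beta,omega Oscillator parameters.
#' @param opts Options list; recognised entries (with defaults):
#'   `T_max` (1000) and `R_max` (1e3) blow-up thresholds, `gamma_max` (10)
#'   continuation limit, `ntst` (50) mesh intervals, `n_tail` (25) maximum
#'   number of tail points used in the fit.
#' @return A list of class `gamma_star_estimate` with fields `gamma_star`,
#'   `bracket`, `period_at_lo`, `method_diagnostics` (fit coefficients and
#'   R^2), and `branch`; or, when no blow-up occurs below `gamma_max`
#'   (parameters of equal sign), a list with `gamma_star = NA` and
#'   `status = "none"`.
#' @export
estimate_gamma_star <- function(alpha, beta, omega, opts = list()) {
  o <- modifyList(list(T_max = 1000, R_max = 1e3, gamma_max = 10,
                       ntst = 50, ncol = 4, n_tail = 25), opts)
  p0 <- osc_params(alpha, beta, 0, omega)
  crit <- hopf_criticality_single(p0)
  if (crit$label == "degenerate")
    stop("degenerate Hopf bifurcation: criticality undefined")
  dir0 <- if (crit$label == "supercritical") 1 else -1
  orb <- orbit_from_hopf(
    list(par_value = 0, im = omega, eigvec = c(1, 1i * omega)),
    params = p0, free = "gamma", eps = 1e-3,
    ntst = o$ntst, ncol = o$ncol)
  br <- continue_periodic_branch(
    orb, free = "gamma", range = c(-o$gamma_max, o$gamma_max),
    opts = list(direction = dir0, T_max = o$T_max, R_max = o$R_max,
                ds0 = 0.02, ds_max = 0.1, adapt_mesh = TRUE,
                par_stall_tol = 1e-9, compute_floquet = FALSE))
  pts <- branch_points_df(br)
  if (br$status == "range" && max(pts$par) >= o$gamma_max - 1e-6)
    return(structure(list(gamma_star = NA_real_, status = "none",
                          reason = sprintf("no blow-up for gamma <= %g", o$gamma_max),
                          branch = br),
                     class = "gamma_star_estimate"))
  # tail: monotone-period end segment of the branch
  Tp <- pts$period; g <- pts$par
  iend <- which.max(Tp)
  sel <- seq(max(1, iend - o$n_tail + 1), iend)
  sel <- sel[g[sel] < g[iend] | seq_along(sel) == length(sel)]
  g_t <- g[sel]; T_t <- Tp[sel]
  keep <- c(diff(T_t) > 0, TRUE) & c(diff(g_t) > 0, TRUE)
  g_t <- g_t[keep]; T_t <- T_t[keep]
  g_end <- g_t[length(g_t)]
  if (length(g_t) < 6)
    stop("continuation terminated with too few tail points for the period-law fit")
  sse <- function(s) {
    gc <- g_end + 10^s
    r <- stats::lm(T_t ~ log(gc - g_t))
    sum(r$residuals^2)
  }
  span <- max(g_end - g_t[1], 1e-8)
  sopt <- stats::optimize(sse, lower = -12, upper = log10(span) + 1)$minimum
  gc <- g_end + 10^sopt
  fit <- stats::lm(T_t ~ log(gc - g_t))
  r2 <- summary(fit)$r.squared
  structure(list(
    gamma_star = gc,
    bracket = c(gamma_lo = g_end, gamma_hi = gc + (gc - g_end)),
    period_at_lo = T_t[length(T_t)],
    method_diagnostics = list(A = unname(coef(fit)[1]), B = -unname(coef(fit)[2]),
                              r_squared = r2, n_tail = length(g_t),
                              criticality = crit$label),
    status = "estimated", branch = br),
    class = "gamma_star_estimate")
}

#' @export
print.gamma_star_estimate <- function(x, ...) {
  if (identical(x$status, "none")) {
    cat("No heteroclinic blow-up:", x$reason, "\n")
  } else {
    cat(sprintf("gamma* = %.8f  (bracket [%.8f, %.8f], period at lower end %.3f)\n",
                x$gamma_star, x$bracket[1], x$bracket[2], x$period_at_lo))
    cat(sprintf("  period law T = %.3f + %.3f * -log(gamma* - gamma), R^2 = %.5f\n",
                x$method_diagnostics$A, x$method_diagnostics$B,
                x$method_diagnostics$r_squared))
  }
  invisible(x)
}
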