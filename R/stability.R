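#' Classify the trivial equilibrium of a single HKB oscillator
#'
#' The origin has Jacobian `[[0, 1], [-omega^2, gamma]]` with eigenvalues
#' `(gamma +- sqrt(gamma^2 - 4 omega^2)) / 2`.  For `|gamma| >= 2 omega` the
#' eigenvalues are real (node); for `|gamma| < 2 omega` they form a complex
#' pair (focus); the sign of `gamma` decides stability and `gamma == 0` (or
#' `|gamma| == 2 omega` exactly) is flagged non-hyperbolic rather than
#' folded into a neighbouring class.
#'
#' @param params An [osc_params()] object (`gamma` may be any real value).
#' @return A list of class `equilibrium_classification` with fields `kind`
#'   (one of `"stable node"`, `"stable focus"`, `"unstable node"`,
#'   `"unstable focus"`, `"non-hyperbolic"`) and `eigenvalues` (complex
#'   pair).
#' @examples
#' classify_trivial_single(osc_params(1, 1, -1, 2))$kind
#' @export
classify_trivial_single <- function(params) {
  g <- params$gamma; w <- params$omega
  disc <- g^2 - 4 * w^2
  lam <- if (disc >= 0) {
    complex(real = (g + c(1, -1) * sqrt(disc)) / 2, imaginary = 0)
  } else {
    complex(real = g / 2, imaginary = c(1, -1) * sqrt(-disc) / 2)
  }
  kind <- if (g == 0 || disc == 0) {
    "non-hyperbolic"
  } else if (disc > 0) {
    if (g < 0) "stable node" else "unstable node"
  } else {
    if (g < 0) "stable focus" else "unstable focus"
  }
  structure(list(kind = kind, eigenvalues = lam, discriminant = disc),
            class = "equilibrium_classification")
}

#' @export
print.equilibrium_classification <- function(x, ...) {
  cat("Trivial equilibrium:", x$kind, "\n eigenvalues:",
      format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' Hopf criticality of the single HKB oscillator
#'
#' At `gamma = 0` the origin undergoes a Hopf bifurcation with
#' transversality `d Re(lambda)/d gamma = 1/2` and first Lyapunov
#' coefficient
#' \deqn{l_1 = \frac{-(\alpha + 3\beta\omega^2)}{2\omega(\omega^2+1)}.}
#' The bifurcation is supercritical for `alpha + 3 beta omega^2 > 0`
#' (`l1 < 0`), subcritical for `< 0`, and degenerate when the combination
#' vanishes exactly.
#'
#' @param params An [osc_params()] object (its `gamma` is ignored; the
#'   coefficient is evaluated at the bifurcation `gamma = 0`).
#' @return A list of class `hopf_criticality` with fields `l1`, `label`
#'   (`"supercritical"`, `"subcritical"` or `"degenerate"`), and
#'   `transversality` (always `1/2`).
#' @examples
#' hopf_criticality_single(osc_params(1, 1, 0, 2))
#' @export
hopf_criticality_single <- function(params) {
  w <- params$omega
  s <- params$alpha + 3 * params$beta * w^2
  l1 <- -s / (2 * w * (w^2 + 1))
  label <- if (s == 0) "degenerate" else if (s > 0) "supercritical" else "subcritical"
  structure(list(l1 = l1, label = label, transversality = 0.5),
            class = "hopf_criticality")
}

#' @export
print.hopf_criticality <- function(x, ...) {
  cat(sprintf("Hopf bifurcation at gamma = 0: %s (l1 = %.6g)\n", x$label, x$l1))
  invisible(x)
}

#' Spectrum of the coupled HKB model at the trivial state
#'
#' For identical oscillators the 4x4 Jacobian at the origin block-
#' diagonalises in sum/difference coordinates `u = x1 +- x2`, and the
#' characteristic polynomial factorises into an in-phase factor
#' `lambda^2 - gamma lambda + omega^2` and an anti-phase factor
#' `lambda^2 - (gamma + 2a) lambda + omega^2`; neither depends on `b`.
#' For heterogeneous eigenfrequencies the eigenvalues of the full Jacobian
#' are returned without mode tags.
#'
#' @param params A [coupled_params()] object.
#' @return A list of class `origin_spectrum` with fields `eigenvalues`
#'   (length 4, sorted by imaginary then real part) and `mode_factors`
#'   (for identical oscillators: quadratic coefficients of the in-phase and
#'   anti-phase factors, with their eigenvalue pairs).
#' @examples
#' origin_spectrum_coupled(coupled_params(1, 1, 0, 2, a = 0, b = 0.5))
#' @export
origin_spectrum_coupled <- function(params) {
  p <- params
  J <- hkb_jacobian(c(0, 0, 0, 0), p)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(Im(ev), Re(ev))]
  factors <- NULL
  if (p$omega1 == p$omega2) {
    quad_roots <- function(trc, det) {
      disc <- as.complex(trc^2 - 4 * det)
      (trc + c(1, -1) * sqrt(disc)) / 2
    }
    factors <- list(
      `in-phase` = list(trace = p$gamma, det = p$omega1^2,
                        eigenvalues = quad_roots(p$gamma, p$omega1^2)),
      `anti-phase` = list(trace = p$gamma + 2 * p$a, det = p$omega1^2,
                          eigenvalues = quad_roots(p$gamma + 2 * p$a, p$omega1^2)))
  }
  structure(list(eigenvalues = ev, mode_factors = factors, jacobian = J),
            class = "origin_spectrum")
}

#' @export
print.origin_spectrum <- function(x, ...) {
  cat("Origin spectrum:", format(x$eigenvalues, digits = 6), "\n")
  if (!is.null(x$mode_factors))
    cat(sprintf(" in-phase factor:  lambda^2 - %g lambda + %g\n anti-phase factor: lambda^2 - %g lambda + %g\n",
                x$mode_factors$`in-phase`$trace, x$mode_factors$`in-phase`$det,
                x$mode_factors$`anti-phase`$trace, x$mode_factors$`anti-phase`$det))
  invisible(x)
}

#' Hopf loci of the trivial state of the coupled model
#'
#' The in-phase mode loses stability at `gamma = 0` and the anti-phase mode
#' at `gamma = -2a`; both loci are independent of the position-weighted
#' coupling `b`.
#'
#' @param a Velocity-coupling strength.
#' @return Named numeric vector `c(gamma_I = 0, gamma_A = -2 * a)`.
#' @examples
#' hopf_loci(0.5)
#' @export
hopf_loci <- function(a) c(gamma_I = 0, gamma_A = -2 * a)
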