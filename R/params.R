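#' Intrinsic parameters of a single HKB oscillator
#'
#' The single HKB oscillator is the planar system
#' \deqn{\dot x = y, \qquad
#'       \dot y = -y(\alpha x^2 + \beta y^2 - \gamma) - \omega^2 x,}
#' a hybrid Rayleigh-Van der Pol oscillator.  `alpha` weights the Van der
#' Pol (position-squared) damping, `beta` the Rayleigh (velocity-squared)
#' damping, `gamma` is the linear anti-damping (oscillations arise for
#' `gamma > 0`), and `omega` (rad/s) sets the eigenfrequency.
#'
#' @param alpha,beta Dimensionless nonlinearity coefficients.
#' @param gamma Linear damping parameter (dimensionless).
#' @param omega Eigenfrequency in rad/s; must be strictly positive.
#' @return An object of class `osc_params`.
#' @examples
#' osc_params(alpha = 1, beta = 1, gamma = 1, omega = 2)
#' @export
osc_params <- function(alpha, beta, gamma, omega) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma, omega = omega)
  validate_params(p, single = TRUE)
  structure(p, class = c("osc_params", "hkb_params"))
}

#' Parameters of the coupled (two-oscillator) HKB model
#'
#' Two HKB oscillators coupled through
#' \deqn{I_{12} = (a + b(x_1-x_2)^2)(y_1-y_2), \qquad I_{21} = -I_{12},}
#' with per-oscillator eigenfrequencies `omega1`, `omega2`.  The
#' identical-oscillator model is the sub-case `omega1 == omega2` (the
#' default when only `omega` is given).
#'
#' @inheritParams osc_params
#' @param omega Common eigenfrequency (rad/s); shorthand that sets both
#'   `omega1` and `omega2`.
#' @param omega1,omega2 Eigenfrequencies of oscillators 1 and 2 (rad/s).
#' @param a Velocity-coupling strength.
#' @param b Position-weighted coupling strength.
#' @return An object of class `coupled_params`.
#' @examples
#' coupled_params(alpha = 1, beta = 1, gamma = 1, omega = 2, a = 0.5, b = -0.5)
#' @export
coupled_params <- function(alpha, beta, gamma, omega = NULL,
                           omega1 = omega, omega2 = omega, a, b) {
  if (is.null(omega1) || is.null(omega2))
    stop("supply either `omega` or both `omega1` and `omega2`")
  p <- list(alpha = alpha, beta = beta, gamma = gamma,
            omega1 = omega1, omega2 = omega2, a = a, b = b)
  validate_params(p, single = FALSE)
  structure(p, class = c("coupled_params", "hkb_params"))
}

validate_params <- function(p, single) {
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stop("all parameters must be finite real numbers")
  if (single) {
    if (p$omega <= 0) stop("omega must be strictly positive")
  } else {
    if (p$omega1 <= 0 || p$omega2 <= 0)
      stop("omega1 and omega2 must be strictly positive")
  }
  invisible(p)
}

#' @export
print.osc_params <- function(x, ...) {
  cat(sprintf(
    "Single HKB oscillator: alpha=%g beta=%g gamma=%g omega=%g\n",
    x$alpha, x$beta, x$gamma, x$omega))
  invisible(x)
}

#' @export
print.coupled_params <- function(x, ...) {
  cat(sprintf(
    "Coupled HKB model: alpha=%g beta=%g gamma=%g omega1=%g omega2=%g a=%g b=%g%s\n",
    x$alpha, x$beta, x$gamma, x$omega1, x$omega2, x$a, x$b,
    if (x$omega1 == x$omega2) " (identical oscillators)" else ""))
  invisible(x)
}

is_coupled <- function(p) inherits(p, "coupled_params")

# Replace one named parameter; `ratio` means omega1/omega2 at fixed omega1.
set_param <- function(p, name, value) {
  if (name == "ratio") {
    stopifnot(is_coupled(p))
    p$omega2 <- p$omega1 / value
  } else if (name == "omega" && is_coupled(p)) {
    p$omega1 <- p$omega2 <- value
  } else {
    stopifnot(name %in% names(p))
    p[[name]] <- value
  }
  p
}

get_param <- function(p, name) {
  if (name == "ratio") return(p$omega1 / p$omega2)
  if (name == "omega" && is_coupled(p)) return(p$omega1)
  p[[name]]
}
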