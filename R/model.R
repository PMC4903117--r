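#' Evaluate the HKB vector field
#'
#' Right-hand side of the single oscillator (state `(x, y)`) or of the
#' coupled four-dimensional system (state `(x1, x2, y1, y2)`), including the
#' heterogeneous case `omega1 != omega2` in which the restoring term of
#' oscillator i uses its own eigenfrequency.
#'
#' @param state Numeric state vector: length 2 for `osc_params`, length 4
#'   for `coupled_params`, ordered `(x1, x2, y1, y2)`.
#' @param params An [osc_params()] or [coupled_params()] object.
#' @return The state derivative, a numeric vector of the same length.
#' @examples
#' hkb_rhs(c(1, 1), osc_params(1, 1, 1, 2))
#' @export
hkb_rhs <- function(state, params) {
  check_state(state, params)
  m <- model_for(params)
  unname(drop(m$f(matrix(state, ncol = 1), params)))
}

#' Evaluate the Jacobian of the HKB vector field
#'
#' Analytic partial derivatives of [hkb_rhs()].  At the single-oscillator
#' origin this reduces to `[[0, 1], [-omega^2, gamma]]`, the matrix whose
#' eigenvalues organise the Hopf bifurcation of the trivial state.
#'
#' @inheritParams hkb_rhs
#' @return A 2x2 or 4x4 numeric matrix.
#' @examples
#' hkb_jacobian(c(0, 0), osc_params(1, 1, 1, 2))
#' @export
hkb_jacobian <- function(state, params) {
  check_state(state, params)
  m <- model_for(params)
  unname(m$jac(matrix(state, ncol = 1), params)[, , 1])
}

#' Coupling terms of the HKB model
#'
#' The HKB coupling functions
#' `I12 = (a + b(x1-x2)^2)(y1-y2)` and `I21 = (a + b(x2-x1)^2)(y2-y1)`.
#' They are antisymmetric: `I12 + I21 == 0` for every state.
#'
#' @param state Coupled state `(x1, x2, y1, y2)`.
#' @param a,b Coupling coefficients.
#' @return Named numeric vector `c(I12, I21)`.
#' @examples
#' coupling_terms(c(0, 0, 1, -1), a = 0.5, b = 0.5)
#' @export
coupling_terms <- function(state, a, b) {
  if (!all(is.finite(state))) blowup_error(state)
  d <- state[1] - state[2]
  i12 <- (a + b * d^2) * (state[3] - state[4])
  c(I12 = i12, I21 = -i12)
}

check_state <- function(state, params) {
  n <- if (is_coupled(params)) 4L else 2L
  if (length(state) != n)
    stop(sprintf("state must have length %d for this model", n))
  if (!all(is.finite(state))) blowup_error(state)
  invisible(state)
}

blowup_error <- function(state) {
  msg <- if (all(is.finite(state)))
    "state exceeded the blow-up radius: trajectory blow-up"
  else sprintf("non-finite state component (indices: %s): trajectory blow-up",
               paste(which(!is.finite(state)), collapse = ", "))
  stop(structure(
    class = c("hkb_blowup_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), state = state)))
}

# ---------------------------------------------------------------------------
# Internal vectorised model objects used by the collocation/continuation core.
# Each model is a list with
#   n     state dimension
#   f     (n x K state matrix, params) -> n x K derivative matrix
#   jac   (n x K, params) -> n x n x K array of Jacobians
#   dpar  (n x K, params, name) -> n x K derivative wrt one parameter
#   embed optional map from reduced profile to the full 4D profile
# The "antiphase" and "inphase" models are the exact restrictions of the
# coupled identical system to its invariant manifolds x2 = -x1 and x2 = x1:
# a single oscillator with alpha_eff = alpha - 8b, gamma_eff = gamma + 2a
# (anti-phase), or the uncoupled single oscillator (in-phase).

model_single <- function() {
  list(
    type = "single", n = 2L,
    f = function(u, p) {
      x <- u[1, ]; y <- u[2, ]
      rbind(y, -y * (p$alpha * x^2 + p$beta * y^2 - p$gamma) - p$omega^2 * x)
    },
    jac = function(u, p) {
      K <- ncol(u); x <- u[1, ]; y <- u[2, ]
      A <- array(0, c(2, 2, K))
      A[1, 2, ] <- 1
      A[2, 1, ] <- -2 * p$alpha * x * y - p$omega^2
      A[2, 2, ] <- -(p$alpha * x^2 + 3 * p$beta * y^2 - p$gamma)
      A
    },
    dpar = function(u, p, name) {
      x <- u[1, ]; y <- u[2, ]; z <- numeric(ncol(u))
      switch(name,
        gamma = rbind(z, y),
        alpha = rbind(z, -x^2 * y),
        beta  = rbind(z, -y^3),
        omega = rbind(z, -2 * p$omega * x),
        stop("unknown free parameter: ", name))
    })
}

model_coupled <- function() {
  list(
    type = "coupled", n = 4L,
    f = function(u, p) {
      x1 <- u[1, ]; x2 <- u[2, ]; y1 <- u[3, ]; y2 <- u[4, ]
      cpl <- (p$a + p$b * (x1 - x2)^2) * (y1 - y2)
      rbind(y1, y2,
            cpl - (y1 * (p$alpha * x1^2 + p$beta * y1^2 - p$gamma) + p$omega1^2 * x1),
            -cpl - (y2 * (p$alpha * x2^2 + p$beta * y2^2 - p$gamma) + p$omega2^2 * x2))
    },
    jac = function(u, p) {
      K <- ncol(u)
      x1 <- u[1, ]; x2 <- u[2, ]; y1 <- u[3, ]; y2 <- u[4, ]
      d <- x1 - x2; cb <- p$a + p$b * d^2; dv <- y1 - y2
      A <- array(0, c(4, 4, K))
      A[1, 3, ] <- 1
      A[2, 4, ] <- 1
      A[3, 1, ] <- 2 * p$b * d * dv - 2 * p$alpha * x1 * y1 - p$omega1^2
      A[3, 2, ] <- -2 * p$b * d * dv
      A[3, 3, ] <- cb - (p$alpha * x1^2 + 3 * p$beta * y1^2 - p$gamma)
      A[3, 4, ] <- -cb
      A[4, 1, ] <- -2 * p$b * d * dv
      A[4, 2, ] <- 2 * p$b * d * dv - 2 * p$alpha * x2 * y2 - p$omega2^2
      A[4, 3, ] <- -cb
      A[4, 4, ] <- cb - (p$alpha * x2^2 + 3 * p$beta * y2^2 - p$gamma)
      A
    },
    dpar = function(u, p, name) {
      x1 <- u[1, ]; x2 <- u[2, ]; y1 <- u[3, ]; y2 <- u[4, ]
      z <- numeric(ncol(u)); d <- x1 - x2; dv <- y1 - y2
      switch(name,
        gamma = rbind(z, z, y1, y2),
        a     = rbind(z, z, dv, -dv),
        b     = rbind(z, z, d^2 * dv, -d^2 * dv),
        alpha = rbind(z, z, -x1^2 * y1, -x2^2 * y2),
        beta  = rbind(z, z, -y1^3, -y2^3),
        omega = rbind(z, z, -2 * p$omega1 * x1, -2 * p$omega2 * x2),
        omega2 = rbind(z, z, z, -2 * p$omega2 * x2),
        # ratio r = omega1/omega2 with omega1 fixed: omega2 = omega1 / r
        ratio = {
          r <- p$omega1 / p$omega2
          rbind(z, z, z, 2 * p$omega1 * p$omega2 * x2 / r^2)
        },
        stop("unknown free parameter: ", name))
    })
}

# planar restriction helpers ------------------------------------------------

reduced_osc <- function(p, manifold) {
  if (manifold == "antiphase")
    list(alpha = p$alpha - 8 * p$b, beta = p$beta,
         gamma = p$gamma + 2 * p$a, omega = p$omega1)
  else
    list(alpha = p$alpha, beta = p$beta, gamma = p$gamma, omega = p$omega1)
}

model_reduced <- function(manifold = c("antiphase", "inphase")) {
  manifold <- match.arg(manifold)
  base <- model_single()
  sgn <- if (manifold == "antiphase") -1 else 1
  list(
    type = paste0("reduced_", manifold), n = 2L,
    f = function(u, p) base$f(u, reduced_osc(p, manifold)),
    jac = function(u, p) base$jac(u, reduced_osc(p, manifold)),
    dpar = function(u, p, name) {
      pe <- reduced_osc(p, manifold)
      x <- u[1, ]; y <- u[2, ]; z <- numeric(ncol(u))
      switch(name,
        gamma = rbind(z, y),
        a     = if (manifold == "antiphase") rbind(z, 2 * y) else rbind(z, z),
        b     = if (manifold == "antiphase") rbind(z, 8 * x^2 * y) else rbind(z, z),
        alpha = rbind(z, -x^2 * y),
        beta  = rbind(z, -y^3),
        omega = rbind(z, -2 * pe$omega * x),
        stop("unknown free parameter: ", name))
    },
    embed = function(u) rbind(u[1, ], sgn * u[1, ], u[2, ], sgn * u[2, ]))
}

model_for <- function(params) {
  if (is_coupled(params)) model_coupled() else model_single()
}
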