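# Shared fixtures and small oracles used across the suite.

fd_jacobian <- function(state, params, h = 1e-6) {
  n <- length(state)
  sapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- h
    (hkb_rhs(state + e, params) - hkb_rhs(state - e, params)) / (2 * h)
  })
}

random_states <- function(n, dim, scale = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) runif(dim, -scale, scale))
}

# brute-force root scan of the equator equilibrium condition G4(theta) = 0
equator_roots_bruteforce <- function(alpha, beta, ngrid = 20000) {
  th <- seq(0, 2 * pi, length.out = ngrid + 1)
  g <- equator_flow(th, alpha, beta)
  roots <- c()
  for (i in seq_len(ngrid)) {
    if (g[i] == 0) roots <- c(roots, th[i])
    else if (g[i] * g[i + 1] < 0)
      roots <- c(roots, uniroot(function(t) equator_flow(t, alpha, beta),
                                c(th[i], th[i + 1]), tol = 1e-14)$root)
  }
  roots <- roots %% (2 * pi)
  roots[roots > 2 * pi - 1e-6] <- 0
  sort(unique(round(roots, 8)))
}

# deterministic initial condition known to lie in the phase-locked basin of
# the Fig-11 setting (omega = 2.3)
fig11_pl_ic <- c(0.5, -0.1, 0.3, 0.4)

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

set_b <- function(p, b) coupled_params(p$alpha, p$beta, p$gamma,
                                       omega1 = p$omega1, omega2 = p$omega2,
                                       a = p$a, b = b)
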