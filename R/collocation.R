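# Orthogonal-collocation discretisation of periodic orbits.
#
# An orbit on [0,1] (time rescaled by the period T) is represented by its
# values at NTST*NCOL + 1 representation points: each mesh interval
# [tau_j, tau_j+1] carries a degree-NCOL Lagrange polynomial through NCOL+1
# equally spaced points, collocated at the NCOL Gauss-Legendre nodes of the
# interval.  Unknowns are the profile values, the period and the free
# parameter; equations are the collocation conditions, periodicity, an
# integral phase condition and one closure row (fixed parameter, fixed
# amplitude, or pseudo-arclength).

gauss_legendre <- function(m) {
  if (m == 1) return(list(z = 0.5, w = 1))
  k <- seq_len(m - 1)
  b <- k / sqrt(4 * k^2 - 1)
  Jm <- matrix(0, m, m)
  Jm[cbind(k, k + 1)] <- b
  Jm[cbind(k + 1, k)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  ord <- order(e$values)
  list(z = (e$values[ord] + 1) / 2, w = (e$vectors[1, ord])^2)
}

lagrange_matrices <- function(nodes, z) {
  m1 <- length(nodes); q <- length(z)
  L <- matrix(0, q, m1); D <- matrix(0, q, m1)
  for (i in seq_len(q)) {
    zi <- z[i]
    hit <- which(abs(zi - nodes) < 1e-13)
    if (length(hit) == 1) {
      L[i, hit] <- 1
      for (k in seq_len(m1)) {
        if (k == hit) {
          D[i, k] <- sum(1 / (nodes[hit] - nodes[-hit]))
        } else {
          oth <- setdiff(seq_len(m1), c(k, hit))
          D[i, k] <- prod(nodes[hit] - nodes[oth]) / prod(nodes[k] - nodes[-k])
        }
      }
    } else {
      d <- zi - nodes
      for (k in seq_len(m1)) {
        L[i, k] <- prod(d[-k]) / prod(nodes[k] - nodes[-k])
        D[i, k] <- L[i, k] * sum(1 / d[-k])
      }
    }
  }
  list(L = L, D = D)
}

# integral of each basis polynomial over [0,1] (for integral inner products)
basis_int_weights <- function(m) {
  g <- gauss_legendre(m + 2)
  lm <- lagrange_matrices((0:m) / m, g$z)
  as.vector(t(lm$L) %*% g$w)
}

# static discretisation context ---------------------------------------------
make_ctx <- function(model, params, free, tau, m) {
  n <- model$n; N <- length(tau) - 1
  g <- gauss_legendre(m)
  lm <- lagrange_matrices((0:m) / m, g$z)
  h <- diff(tau)
  # integration weight of every representation point (composite, shared ends)
  rho <- basis_int_weights(m)
  wint <- numeric(N * m + 1)
  for (j in seq_len(N)) {
    cols <- ((j - 1) * m + 1):((j - 1) * m + m + 1)
    wint[cols] <- wint[cols] + h[j] * rho
  }
  list(model = model, params = params, free = free, tau = tau, h = h,
       m = m, n = n, N = N, M = N * m,
       gz = g$z, gw = g$w, Lc = lm$L, Dc = lm$D, wint = wint)
}

ctx_weights <- function(ctx, w_period = 0, w_par = 1) {
  c(rep(ctx$wint, each = ctx$n), w_period, w_par)
}

# phase-condition coefficients from a reference profile (linear functional)
ctx_phase_coef <- function(ctx, Uref) {
  n <- ctx$n; m <- ctx$m
  pc <- matrix(0, n, ctx$M + 1)
  for (j in seq_len(ctx$N)) {
    cols <- ((j - 1) * m + 1):((j - 1) * m + m + 1)
    dUg <- (Uref[, cols, drop = FALSE] %*% t(ctx$Dc)) / ctx$h[j]
    for (i in seq_len(m)) {
      w <- ctx$h[j] * ctx$gw[i]
      pc[, cols] <- pc[, cols] + w * outer(dUg[, i], ctx$Lc[i, ])
    }
  }
  as.vector(pc)
}

pack_z <- function(U, period, par) c(as.vector(U), period, par)
unpack_z <- function(z, ctx) {
  np <- ctx$n * (ctx$M + 1)
  list(U = matrix(z[seq_len(np)], ctx$n, ctx$M + 1),
       period = z[np + 1], par = z[np + 2])
}

# residual + Jacobian of the full collocation system ------------------------
# mode: list(type = "fixed"|"amplitude"|"arclength", ...)
po_FJ <- function(z, ctx, phase_coef, mode) {
  n <- ctx$n; m <- ctx$m; N <- ctx$N; M <- ctx$M
  s <- unpack_z(z, ctx)
  U <- s$U; T <- s$period; lam <- s$par
  pars <- set_param(ctx$params, ctx$free, lam)
  nz <- length(z)
  Fv <- numeric(nz)
  J <- matrix(0, nz, nz)
  icolT <- n * (M + 1) + 1; icolL <- icolT + 1
  for (j in seq_len(N)) {
    cols <- ((j - 1) * m + 1):((j - 1) * m + m + 1)
    Ub <- U[, cols, drop = FALSE]
    Ug <- Ub %*% t(ctx$Lc)
    dUg <- (Ub %*% t(ctx$Dc)) / ctx$h[j]
    Fg <- ctx$model$f(Ug, pars)
    Ag <- ctx$model$jac(Ug, pars)
    dp <- ctx$model$dpar(Ug, pars, ctx$free)
    r0 <- (j - 1) * m * n
    Fv[r0 + seq_len(m * n)] <- as.vector(dUg - T * Fg)
    for (i in seq_len(m)) {
      ri <- r0 + (i - 1) * n + seq_len(n)
      Ai <- Ag[, , i]
      for (k in seq_len(m + 1)) {
        ci <- (cols[k] - 1) * n + seq_len(n)
        blk <- -T * ctx$Lc[i, k] * Ai
        dd <- ctx$Dc[i, k] / ctx$h[j]
        diag(blk) <- diag(blk) + dd
        J[ri, ci] <- J[ri, ci] + blk
      }
      J[ri, icolT] <- -Fg[, i]
      J[ri, icolL] <- -T * dp[, i]
    }
  }
  rper <- M * n + seq_len(n)
  Fv[rper] <- U[, M + 1] - U[, 1]
  J[cbind(rper, M * n + seq_len(n))] <- 1
  J[cbind(rper, seq_len(n))] <- J[cbind(rper, seq_len(n))] - 1
  rph <- M * n + n + 1
  Fv[rph] <- sum(phase_coef * as.vector(U))
  J[rph, seq_len(n * (M + 1))] <- phase_coef
  rcl <- rph + 1
  if (mode$type == "fixed") {
    Fv[rcl] <- lam - mode$par_value
    J[rcl, icolL] <- 1
  } else if (mode$type == "fixed_period") {
    Fv[rcl] <- T - mode$period
    J[rcl, icolT] <- 1
  } else if (mode$type == "amplitude") {
    wi <- ctx$wint / sum(ctx$wint)
    um <- as.vector(U %*% wi)
    Ud <- U - um
    amp2 <- sum(rep(ctx$wint, each = n) * as.vector(Ud)^2)
    Fv[rcl] <- amp2 - mode$eps^2
    J[rcl, seq_len(n * (M + 1))] <- 2 * rep(ctx$wint, each = n) * as.vector(Ud)
  } else if (mode$type == "arclength") {
    w <- mode$weights
    Fv[rcl] <- sum(w * mode$tangent * (z - mode$z0)) - mode$ds
    J[rcl, ] <- w * mode$tangent
  } else stop("unknown closure mode")
  list(F = Fv, J = J)
}

po_newton <- function(z, ctx, phase_coef, mode, tol = 1e-9, maxit = 12) {
  res_prev <- Inf
  for (it in seq_len(maxit)) {
    fj <- po_FJ(z, ctx, phase_coef, mode)
    res <- max(abs(fj$F))
    dz <- try(solve(fj$J, -fj$F), silent = TRUE)
    if (inherits(dz, "try-error"))
      return(list(ok = FALSE, z = z, iter = it, res = res, J = fj$J))
    z <- z + dz
    step <- max(abs(dz))
    if (step < tol && res < sqrt(tol))
      return(list(ok = TRUE, z = z, iter = it, res = res, J = fj$J))
    if (res > 1e4 * max(res_prev, 1) || !is.finite(res))
      return(list(ok = FALSE, z = z, iter = it, res = res, J = fj$J))
    res_prev <- res
  }
  list(ok = FALSE, z = z, iter = maxit, res = res_prev, J = NULL)
}

# branch tangent through a bordered solve: replace the closure row of J by
# the previous (weighted) tangent and solve for the unit tangent.
po_tangent <- function(J, ctx, prev_tangent, weights) {
  nz <- nrow(J)
  Jt <- J
  Jt[nz, ] <- weights * prev_tangent
  rhs <- c(numeric(nz - 1), 1)
  t_new <- try(solve(Jt, rhs), silent = TRUE)
  if (inherits(t_new, "try-error")) return(NULL)
  t_new / sqrt(sum(weights * t_new^2))
}

# monodromy matrix by interval condensation of the linearised collocation
# equations; `model`/`params` may differ from the discretisation (e.g. the
# full 4D system along an orbit embedded from an invariant manifold).
po_monodromy <- function(U, tau, m, period, model, pars) {
  n <- model$n; N <- length(tau) - 1
  g <- gauss_legendre(m)
  lm <- lagrange_matrices((0:m) / m, g$z)
  h <- diff(tau)
  Mono <- diag(n)
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
    X <- try(solve(B, -C), silent = TRUE)
    if (inherits(X, "try-error")) return(NULL)
    Mj <- X[(m - 1) * n + seq_len(n), , drop = FALSE]
    Mono <- Mj %*% Mono
  }
  Mono
}

floquet_of <- function(Mono) {
  if (is.null(Mono)) return(NULL)
  mu <- eigen(Mono, only.values = TRUE)$values
  itriv <- which.min(Mod(mu - 1))
  list(all = mu, trivial = mu[itriv], nontrivial = mu[-itriv],
       stable = all(Mod(mu[-itriv]) < 1 + 1e-8))
}

# evaluate the collocation polynomial at arbitrary times t in [0,1]
profile_eval <- function(U, tau, m, tq) {
  n <- nrow(U); N <- length(tau) - 1
  out <- matrix(0, n, length(tq))
  tq <- pmin(pmax(tq, 0), 1)
  j <- pmin(findInterval(tq, tau, rightmost.closed = TRUE), N)
  s <- (tq - tau[j]) / (tau[j + 1] - tau[j])
  for (i in seq_along(tq)) {
    lm <- lagrange_matrices((0:m) / m, s[i])
    cols <- ((j[i] - 1) * m + 1):((j[i] - 1) * m + m + 1)
    out[, i] <- U[, cols, drop = FALSE] %*% as.vector(lm$L)
  }
  out
}

# redistribute the mesh to equidistribute profile arclength (blended with
# the old mesh for stability), and re-interpolate the profile
remesh_orbit <- function(U, tau, m, blend = 0.5) {
  N <- length(tau) - 1
  tpts <- rep_point_times(tau, m)
  du <- sqrt(colSums((U[, -1, drop = FALSE] - U[, -ncol(U), drop = FALSE])^2))
  seg <- du + 1e-3 * diff(tpts) / mean(diff(tpts)) * mean(du + 1e-12)
  cum <- c(0, cumsum(seg))
  cum <- cum / cum[length(cum)]
  tau_new <- stats::approx(cum, tpts, xout = seq(0, 1, length.out = N + 1),
                           ties = "ordered")$y
  tau_new[1] <- 0; tau_new[N + 1] <- 1
  tau_new <- blend * tau_new + (1 - blend) * tau
  tau_new <- cummax(tau_new)  # guard monotonicity
  if (any(diff(tau_new) <= 0)) return(list(U = U, tau = tau))
  Unew <- profile_eval(U, tau, m, rep_point_times(tau_new, m))
  list(U = Unew, tau = tau_new)
}

rep_point_times <- function(tau, m) {
  N <- length(tau) - 1
  tp <- numeric(N * m + 1)
  for (j in seq_len(N)) {
    idx <- ((j - 1) * m + 1):((j - 1) * m + m + 1)
    tp[idx] <- tau[j] + (0:m) / m * (tau[j + 1] - tau[j])
  }
  tp
}

# peak time (in scaled time [0,1)) of one profile component, by quadratic
# interpolation around the maximum representation point
profile_peak_time <- function(U, tau, m, comp) {
  tp <- rep_point_times(tau, m)
  x <- U[comp, ]
  i <- which.max(x[-length(x)])  # last point duplicates the first
  np <- length(x) - 1
  im <- if (i == 1) np else i - 1
  ip <- if (i == np) 1 else i + 1
  tm <- tp[im]; t0 <- tp[i]; tpl <- tp[ip]
  if (im == np) tm <- tm - 1
  if (ip == 1) tpl <- tpl + 1
  # quadratic through three points (possibly unequal spacing)
  y <- c(x[im], x[i], x[ip]); tt <- c(tm, t0, tpl)
  d <- (tt[3] - tt[2]) * (y[1] - y[2]) - (tt[1] - tt[2]) * (y[3] - y[2])
  if (abs(d) < 1e-300) return(t0 %% 1)
  num <- (tt[3] - tt[2])^2 * (y[1] - y[2]) - (tt[1] - tt[2])^2 * (y[3] - y[2])
  (tt[2] + 0.5 * num / d) %% 1
}

# signed relative phase (degrees) of a coupled-profile orbit
profile_lag <- function(U, tau, m) {
  if (nrow(U) != 4) return(NA_real_)
  t1 <- profile_peak_time(U, tau, m, 1)
  t2 <- profile_peak_time(U, tau, m, 2)
  lag <- 360 * (t2 - t1)
  ((lag + 180) %% 360) - 180
}
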