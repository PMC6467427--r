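## Implicit-Euler forward propagation.
##
## The transcribed problem's equality constraints are block lower
## triangular in the states: given parameters, each implicit Euler step
## x_{j} = x_{j-1} + h f(x_j, theta) determines x_j through a small
## nonlinear equation.  Propagating forward with Newton's method
## eliminates the states exactly (the constraint residual at the
## propagated states is zero to Newton tolerance), which is the basis of
## the reduced-space solver and of synthetic full-space test points.

# local parameter vector layout for an experiment with n members:
# (mu_1, a_11..a_1n, ..., mu_n, a_n1..a_nn[, K_11..K_1n, ..., K_nn])
local_theta_map <- function(members_idx, S, model_form) {
  n <- length(members_idx)
  idx <- integer(0)
  for (s in members_idx)
    idx <- c(idx, (s - 1L) * (S + 1L) + 1L,
             (s - 1L) * (S + 1L) + 1L + members_idx)
  if (model_form == "saturable")
    for (s in members_idx)
      idx <- c(idx, S^2 + S + (s - 1L) * S + members_idx)
  idx
}

local_lp <- function(theta_local, n, model_form) {
  lp <- list(mu = numeric(n), alpha = matrix(0, n, n))
  for (s in seq_len(n)) {
    off <- (s - 1L) * (n + 1L)
    lp$mu[s] <- theta_local[off + 1L]
    lp$alpha[s, ] <- theta_local[off + 1L + seq_len(n)]
  }
  if (model_form == "saturable")
    lp$K <- matrix(theta_local[n * (n + 1L) + seq_len(n^2)], n, n,
                   byrow = TRUE)
  lp
}

# derivative of f with respect to the local parameter vector (n x p)
model_ftheta <- function(x, lp, model_form) {
  n <- length(x)
  p <- if (model_form == "glv") n * (n + 1L) else n * (2L * n + 1L)
  ft <- matrix(0, n, p)
  if (model_form == "glv") {
    for (s in seq_len(n)) {
      off <- (s - 1L) * (n + 1L)
      ft[s, off + 1L] <- x[s]
      ft[s, off + 1L + seq_len(n)] <- x * x[s]
    }
  } else {
    xm <- matrix(x, n, n, byrow = TRUE)
    g <- xm / (lp$K + xm)
    gK <- -xm / (lp$K + xm)^2
    for (s in seq_len(n)) {
      off <- (s - 1L) * (n + 1L)
      ft[s, off + 1L] <- x[s]
      ft[s, off + 1L + seq_len(n)] <- g[s, ] * x[s]
      koff <- n * (n + 1L) + (s - 1L) * n
      ft[s, koff + seq_len(n)] <- lp$alpha[s, ] * gK[s, ] * x[s]
    }
  }
  ft
}

# lambda-weighted second derivative of f over (x, theta_local):
# returns the (n+p) x (n+p) symmetric matrix sum_s lam_s * d2 f_s
model_f2sum <- function(x, lp, model_form, lam) {
  n <- length(x)
  p <- if (model_form == "glv") n * (n + 1L) else n * (2L * n + 1L)
  q <- n + p
  M <- matrix(0, q, q)
  add <- function(i, j, v) {
    M[i, j] <<- M[i, j] + v
    if (i != j) M[j, i] <<- M[j, i] + v
  }
  if (model_form == "glv") {
    for (s in seq_len(n)) {
      ls <- lam[s]
      if (ls == 0) next
      off <- n + (s - 1L) * (n + 1L)
      for (a in seq_len(n)) {
        # d2 f_s / dx_a dx_b = a_{sb} d_{as} + a_{sa} d_{bs}
        if (a == s) M[s, s] <- M[s, s] + 2 * ls * lp$alpha[s, s]
        else add(a, s, ls * lp$alpha[s, a])
      }
      add(s, off + 1L, ls)                       # x_s - mu_s
      for (j in seq_len(n)) {
        cj <- off + 1L + j
        add(s, cj, ls * x[j])                    # x_s - a_sj
        add(j, cj, ls * x[s])                    # x_j - a_sj
      }
    }
  } else {
    xm <- matrix(x, n, n, byrow = TRUE)
    den <- lp$K + xm
    G <- xm / den
    Gx <- lp$K / den^2
    GK <- -xm / den^2
    Gxx <- -2 * lp$K / den^3
    GKK <- 2 * xm / den^3
    GxK <- (xm - lp$K) / den^3
    for (s in seq_len(n)) {
      ls <- lam[s]
      if (ls == 0) next
      off <- n + (s - 1L) * (n + 1L)
      koff <- n + n * (n + 1L) + (s - 1L) * n
      for (a in seq_len(n)) {
        if (a == s) M[s, s] <- M[s, s] + 2 * ls * lp$alpha[s, s] * Gx[s, s]
        else add(a, s, ls * lp$alpha[s, a] * Gx[s, a])  # x_a x_s cross
        M[a, a] <- M[a, a] + ls * lp$alpha[s, a] * Gxx[s, a] * x[s]
      }
      add(s, off + 1L, ls)                           # x_s - mu_s
      for (j in seq_len(n)) {
        cj <- off + 1L + j
        add(s, cj, ls * G[s, j])                     # x_s - a_sj
        add(j, cj, ls * Gx[s, j] * x[s])             # x_j - a_sj
        kj <- koff + j
        add(s, kj, ls * lp$alpha[s, j] * GK[s, j])   # x_s - K_sj
        add(j, kj, ls * lp$alpha[s, j] * GxK[s, j] * x[s])  # x_j - K_sj
        add(cj, kj, ls * GK[s, j] * x[s])            # a_sj - K_sj
        M[kj, kj] <- M[kj, kj] +
          ls * lp$alpha[s, j] * GKK[s, j] * x[s]     # K_sj - K_sj
      }
    }
  }
  M
}

# Scalar gLV implicit Euler step: root of h*a*z^2 + (h*mu - 1)*z + x.
# Among the real nonnegative roots, the one closest to the previous
# state (the root that deforms continuously from x as h -> 0) is taken;
# NULL when no nonnegative root exists (step infeasible under the
# positivity bound).
implicit_step_scalar_glv <- function(x, h, mu, alpha) {
  A <- h * alpha; B <- h * mu - 1; C <- x
  if (abs(A) < 1e-14) {
    z <- -C / B
    return(if (is.finite(z) && z >= -1e-12) max(z, 0) else NULL)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NULL)
  q <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
  roots <- c(q / A, if (q != 0) C / q else 0)
  roots <- roots[is.finite(roots) & roots >= -1e-12]
  if (!length(roots)) return(NULL)
  max(roots[which.min(abs(roots - x))], 0)
}

# General implicit Euler step by Newton iteration; several starting
# points are tried and nonnegative roots are preferred.
implicit_step_newton <- function(xp, h, lp, model_form, newton_tol,
                                 max_newton, state_cap) {
  n <- length(xp)
  In <- diag(n)
  pred <- xp + h * model_f(xp, lp, model_form)
  starts <- list(ifelse(is.finite(pred), pmax(pred, 0), xp), xp,
                 pmax(xp, 1e-6))
  fallback <- NULL
  rnorm_at <- function(z) {
    r <- z - xp - h * model_f(z, lp, model_form)
    if (any(!is.finite(r))) Inf else max(abs(r))
  }
  for (z0 in starts) {
    z <- z0
    converged <- FALSE
    rmax <- rnorm_at(z)
    for (it in seq_len(max_newton)) {
      if (!is.finite(rmax) || max(abs(z)) > state_cap) break
      if (rmax < newton_tol ||
          (it == max_newton && rmax < 1e-8)) {
        converged <- TRUE; break
      }
      r <- z - xp - h * model_f(z, lp, model_form)
      A <- In - h * model_fx(z, lp, model_form)
      dz <- tryCatch(solve(A, r), error = function(e) NULL)
      if (is.null(dz) || any(!is.finite(dz))) break
      accepted <- FALSE
      t <- 1
      for (ls in 1:8) {              # damped line search on the residual
        zt <- z - t * dz
        rn <- rnorm_at(zt)
        if (rn < rmax) { z <- zt; rmax <- rn; accepted <- TRUE; break }
        t <- t / 2
      }
      if (!accepted) { converged <- rmax < 1e-8; break }
    }
    if (converged) {
      if (min(z) >= -1e-9) return(pmax(z, 0))
      if (is.null(fallback)) fallback <- z
    }
  }
  # accept a marginally negative root; larger violations fail the step
  if (!is.null(fallback) && min(fallback) > -1e-6) return(fallback)
  NULL
}

# Forward implicit-Euler propagation over a grid.
# Returns list(ok, states [J x n], sens [J x n x p array] or NULL,
# fail_node).  The compiled kernel is the default; the pure-R
# implementation below is retained as the reference oracle.
propagate_grid <- function(lp, grid, x0, model_form, sens = FALSE,
                           newton_tol = 1e-12, max_newton = 30L,
                           state_cap = 1e6) {
  kc <- match(grid$kind, c("init", "step", "dilution")) - 1L
  out <- .Call(C_propagate, as.numeric(grid$times), kc,
               as.numeric(grid$dilution_factor %||% 1),
               as.numeric(x0), as.numeric(lp$mu),
               matrix(as.numeric(lp$alpha), length(x0)),
               if (model_form == "saturable")
                 matrix(as.numeric(lp$K), length(x0)) else NULL,
               isTRUE(sens), as.numeric(newton_tol),
               as.integer(max_newton), as.numeric(state_cap))
  list(ok = out$ok, states = out$states, sens = out$sens,
       fail_node = attr(out, "fail_node"))
}

propagate_grid_r <- function(lp, grid, x0, model_form, sens = FALSE,
                             newton_tol = 1e-12, max_newton = 30L,
                             state_cap = 1e6) {
  J <- length(grid$times)
  n <- length(x0)
  p <- if (model_form == "glv") n * (n + 1L) else n * (2L * n + 1L)
  states <- matrix(NA_real_, J, n)
  states[1L, ] <- x0
  Ssens <- if (sens) array(0, c(J, n, p)) else NULL
  In <- diag(n)
  scalar_glv <- n == 1L && model_form == "glv"
  for (j in 2:J) {
    if (grid$kind[j] == "dilution") {
      states[j, ] <- grid$dilution_factor * states[j - 1L, ]
      if (sens) Ssens[j, , ] <- grid$dilution_factor * Ssens[j - 1L, , ]
      next
    }
    h <- grid$times[j] - grid$times[j - 1L]
    xp <- states[j - 1L, ]
    z <- if (scalar_glv)
      implicit_step_scalar_glv(xp, h, lp$mu[1L], lp$alpha[1L, 1L])
    else implicit_step_newton(xp, h, lp, model_form, newton_tol,
                              max_newton, state_cap)
    if (is.null(z))
      return(list(ok = FALSE, states = states, sens = Ssens,
                  fail_node = j, fail_time = grid$times[j]))
    states[j, ] <- z
    if (sens) {
      A <- In - h * model_fx(z, lp, model_form)
      rhs <- matrix(Ssens[j - 1L, , ], n) +
        h * model_ftheta(z, lp, model_form)
      Sj <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(Sj) || any(!is.finite(Sj)))
        return(list(ok = FALSE, states = states, sens = Ssens,
                    fail_node = j, fail_time = grid$times[j]))
      Ssens[j, , ] <- Sj
    }
  }
  list(ok = TRUE, states = states, sens = Ssens, fail_node = NA_integer_)
}
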