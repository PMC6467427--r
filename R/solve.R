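#' Solver options
#'
#' @param max_iterations iteration cap for the optimizer.
#' @param tol convergence tolerance used for optimality reporting.
#' @param backend optimizer backend identifier (currently
#'   `"reduced-nlminb"`: reduced-space elimination of the states with a
#'   bound-constrained quasi-Newton parameter search).
#' @param trace print optimizer progress every `trace` iterations (0 =
#'   silent).
#' @return a `solver_options` object.
#' @export
solver_options <- function(max_iterations = 500L, tol = 1e-8,
                           backend = "reduced-nlminb", trace = 0L) {
  if (tol <= 0) stopf("'tol' must be positive")
  structure(list(max_iterations = as.integer(max_iterations), tol = tol,
                 backend = backend, trace = as.integer(trace)),
            class = "solver_options")
}

## reduced objective/gradient over theta; states eliminated by
## implicit-Euler propagation (see propagate.R).  A one-slot cache keyed
## on theta avoids re-propagating when the optimizer asks for the
## objective and the gradient at the same point.
make_reduced <- function(nlp, need_grad = TRUE) {
  pr <- nlp$prior
  p <- nlp$n_theta
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  fail_val <- function(theta) 1e8 * (1 + sum(theta^2))
  fail_grad <- function(theta) 2e8 * theta

  evalpt <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta))
      return(cache$res)
    e <- numeric(length(nlp$exps))
    de <- if (need_grad) matrix(0, length(nlp$exps), p) else NULL
    ok <- TRUE
    props <- vector("list", length(nlp$exps))
    for (k in seq_along(nlp$exps)) {
      ex <- nlp$exps[[k]]
      lp <- local_lp(theta[ex$lmap], ex$n, nlp$model_form)
      pg <- propagate_grid(lp, ex$grid, ex$x0, nlp$model_form,
                           sens = need_grad)
      props[[k]] <- pg
      if (!pg$ok) { ok <- FALSE; break }
      xo <- pg$states[cbind(ex$obs$node, ex$obs$sp)]
      r <- (xo - ex$obs$eta) / ex$obs$sigma^2
      e[k] <- sum(0.5 * (xo - ex$obs$eta)^2 / ex$obs$sigma^2)
      if (need_grad) {
        J <- length(ex$grid$times)
        Sm <- matrix(pg$sens, J * ex$n)   # rows: (node, species) pairs
        rows <- ex$obs$node + J * (ex$obs$sp - 1L)
        de[k, ex$lmap] <- colSums(r * Sm[rows, , drop = FALSE])
      }
    }
    res <- list(ok = ok, e = e, de = de, props = props)
    cache$theta <- theta
    cache$res <- res
    res
  }

  prior_val <- function(theta) switch(pr$form,
    none = 0,
    L2 = 0.5 * sum(((theta - pr$mean) / pr$sd)^2),
    L1 = sum(abs(theta - pr$mean) / pr$sd))
  prior_grad <- function(theta) switch(pr$form,
    none = numeric(p),
    L2 = (theta - pr$mean) / pr$sd^2,
    L1 = sign(theta - pr$mean) / pr$sd)

  # CVaR: minimized-over-gamma objective via the sorted-tail formula
  cvar_parts <- function(e) {
    K <- length(e)
    beta <- nlp$cvar$beta
    m <- ceiling((1 - beta) * K)
    ord <- order(e, decreasing = TRUE)
    wts <- numeric(K)
    if (m > 1) wts[ord[seq_len(m - 1L)]] <- 1 / (1 - beta)
    wts[ord[m]] <- ((1 - beta) * K - (m - 1L)) / (1 - beta)
    list(value = sum(wts * e), weights = wts, gamma = e[ord[m]])
  }

  objective <- function(theta) {
    r <- evalpt(theta)
    if (!r$ok) return(fail_val(theta))
    if (is.null(nlp$cvar)) prior_val(theta) + sum(r$e)
    else prior_val(theta) + cvar_parts(r$e)$value
  }
  gradient <- function(theta) {
    r <- evalpt(theta)
    if (!r$ok) return(fail_grad(theta))
    if (is.null(nlp$cvar)) prior_grad(theta) + colSums(r$de)
    else prior_grad(theta) +
      as.vector(crossprod(r$de, cvar_parts(r$e)$weights))
  }
  list(objective = objective, gradient = gradient, evalpt = evalpt,
       cvar_parts = cvar_parts)
}

## CVaR solves: the k-max objective is piecewise smooth (kinks wherever
## the set of tail experiments changes), which stalls quasi-Newton
## iterations.  The hinge [e_k - gamma]+ is therefore smoothed with a
## softplus of temperature tau, solved jointly over (theta, gamma), and
## tau is annealed towards zero; a final pass at the exact
## sorted-weights objective polishes theta.
solve_cvar_annealed <- function(nlp, red, theta0, lb, ub, options) {
  K <- length(nlp$exps)
  beta <- nlp$cvar$beta
  ctl <- list(iter.max = options$max_iterations,
              eval.max = 10L * options$max_iterations,
              trace = options$trace)
  softplus <- function(u, tau) {
    v <- u / tau
    ifelse(v > 30, u, tau * log1p(exp(pmin(v, 30))))
  }
  sig <- function(u, tau) stats::plogis(u / tau)
  prior_grad_theta <- function(theta) {
    pr <- nlp$prior
    switch(pr$form, none = numeric(length(theta)),
           L2 = (theta - pr$mean) / pr$sd^2,
           L1 = sign(theta - pr$mean) / pr$sd)
  }
  prior_val_theta <- function(theta) {
    pr <- nlp$prior
    switch(pr$form, none = 0,
           L2 = 0.5 * sum(((theta - pr$mean) / pr$sd)^2),
           L1 = sum(abs(theta - pr$mean) / pr$sd))
  }
  obj_s <- function(x, tau) {
    th <- x[-length(x)]; g <- x[length(x)]
    r <- red$evalpt(th)
    if (!r$ok) return(1e8 * (1 + sum(th^2)))
    prior_val_theta(th) + K * g +
      sum(softplus(r$e - g, tau)) / (1 - beta)
  }
  grad_s <- function(x, tau) {
    th <- x[-length(x)]; g <- x[length(x)]
    r <- red$evalpt(th)
    if (!r$ok) return(c(2e8 * th, 0))
    sg <- sig(r$e - g, tau)
    c(prior_grad_theta(th) + as.vector(crossprod(r$de, sg)) / (1 - beta),
      K - sum(sg) / (1 - beta))
  }
  e0 <- red$evalpt(theta0)
  g0 <- if (e0$ok) cvar_objective_value(e0$e, beta)$minimized$gamma else 1
  x <- c(theta0, g0)
  scale <- if (e0$ok) max(stats::sd(e0$e), 1e-2) else 1
  iters <- 0L
  last <- NULL
  for (tau in scale * c(0.3, 0.03, 0.003)) {
    last <- stats::nlminb(x, obj_s, grad_s,
                          lower = c(lb, -Inf), upper = c(ub, Inf),
                          tau = tau, control = ctl)
    x <- last$par
    iters <- iters + last$iterations
  }
  polish <- stats::nlminb(x[-length(x)], red$objective, red$gradient,
                          lower = lb, upper = ub, control = ctl)
  iters <- iters + polish$iterations
  best <- if (polish$objective <= red$objective(x[-length(x)]) + 1e-12)
    polish$par else x[-length(x)]
  list(par = best, objective = red$objective(best),
       convergence = polish$convergence,
       iterations = iters, message = polish$message)
}

#' Default primal initialization
#'
#' States are initialized by linear interpolation of the experiment's
#' own measurements over the grid (floored at a small positive value);
#' parameters start at the prior mean (bound midpoint when no prior is
#' used), projected into the interior of the bounds.  Deterministic
#' given the seed.
#'
#' @param nlp a `glv_nlp`.
#' @param data measurement data frame (defaults to the one transcribed).
#' @param seed integer seed (kept for interface stability; the default
#'   initialization is deterministic).
#' @return full-space initial point `w`.
#' @export
default_initialization <- function(nlp, data = nlp$data, seed = 1L) {
  p <- nlp$n_theta
  lb <- nlp$lb[seq_len(p)]; ub <- nlp$ub[seq_len(p)]
  theta <- if (nlp$prior$form == "none") {
    mid <- (lb + pmin(ub, lb + 20)) / 2
    mid
  } else rep_len(nlp$prior$mean, p)
  pad <- 0.05 * pmin(ub - lb, 2)
  theta <- pmin(pmax(theta, lb + pad), ub - pad)
  w <- numeric(nlp$n_vars)
  w[seq_len(p)] <- theta
  for (ex in nlp$exps) {
    tt <- ex$grid$times
    for (s in seq_len(ex$n)) {
      o <- ex$obs[ex$obs$sp == s, , drop = FALSE]
      pts_t <- c(0, ex$grid$times[o$node])
      pts_x <- c(ex$x0[s], o$eta)
      xs <- if (length(pts_t) > 1L)
        stats::approx(pts_t, pts_x, xout = tt, rule = 2)$y
      else rep(ex$x0[s], length(tt))
      w[ex$var_idx[, s]] <- pmax(xs, 1e-6)
    }
  }
  if (!is.null(nlp$l1_pos)) {
    dev <- theta - rep_len(nlp$prior$mean, p)
    w[nlp$l1_pos] <- pmax(dev, 0)
    w[nlp$l1_neg] <- pmax(-dev, 0)
  }
  if (!is.null(nlp$gamma_idx)) w[nlp$gamma_idx] <- 0
  w
}

extract_theta0 <- function(nlp, initial_point) {
  if (is.null(initial_point)) initial_point <- default_initialization(nlp)
  if (inherits(initial_point, "glv_warm_start"))
    initial_point <- initial_point$w
  if (length(initial_point) == nlp$n_theta) return(as.numeric(initial_point))
  if (length(initial_point) == nlp$n_vars)
    return(as.numeric(initial_point[seq_len(nlp$n_theta)]))
  stopf("initial point must have length %d (theta) or %d (full w)",
        nlp$n_theta, nlp$n_vars)
}

#' Solve a transcribed MAP problem
#'
#' Solves the estimation problem behind the standard NLP callback
#' contract.  The backend eliminates the discretized states by implicit
#' Euler forward propagation (they are uniquely determined by the
#' parameters through the block-triangular constraints) and solves the
#' remaining bound-constrained parameter problem with a quasi-Newton
#' method using analytic sensitivities.  At the solution the full
#' variable vector, the equality multipliers (adjoint solve) and the
#' bound multipliers are reconstructed so the result is a genuine KKT
#' point of the transcribed problem.
#'
#' @param nlp a `glv_nlp` from [transcribe()].
#' @param initial_point full-space vector, parameter vector, warm-start
#'   object, or `NULL` for [default_initialization()].
#' @param options a [solver_options()] object.
#' @return a `solve_result`: `w_star`, `theta_star` (named),
#'   `lambda` (constraint multipliers), `nu` (bound multipliers),
#'   `objective`, `status` (`"optimal"`, `"max_iter"` or `"error"`),
#'   `iterations`, and the constraint residual norm.
#' @export
solve_nlp <- function(nlp, initial_point = NULL,
                      options = solver_options()) {
  p <- nlp$n_theta
  lb <- nlp$lb[seq_len(p)]; ub <- nlp$ub[seq_len(p)]
  if (any(lb >= ub))
    stopf("contradictory parameter bounds (lower >= upper)")
  theta0 <- extract_theta0(nlp, initial_point)
  pad <- 1e-6 * pmin(ub - lb, 1)
  theta0 <- pmin(pmax(theta0, lb + pad), ub - pad)

  red <- make_reduced(nlp)
  res <- if (is.null(nlp$cvar))
    stats::nlminb(theta0, red$objective, red$gradient,
                  lower = lb, upper = ub,
                  control = list(iter.max = options$max_iterations,
                                 eval.max = 10L * options$max_iterations,
                                 trace = options$trace))
  else solve_cvar_annealed(nlp, red, theta0, lb, ub, options)
  status <- if (res$convergence == 0) "optimal"
  else if (grepl("iteration limit|evaluation limit", res$message))
    "max_iter"
  else if (grepl("false convergence|singular convergence", res$message))
    "optimal"
  else "error"
  theta <- res$par
  pt <- red$evalpt(theta)
  if (!pt$ok) {
    return(structure(list(
      w_star = NULL, theta_star = stats::setNames(theta, names(nlp$theta_idx)),
      lambda = NULL, nu = NULL, objective = res$objective,
      status = "error", iterations = res$iterations,
      message = sprintf("state propagation failed (experiment %s)",
                        nlp$exps[[which(!vapply(pt$props, function(z)
                          isTRUE(z$ok), logical(1)))[1L]]]$id),
      constraint_violation = NA_real_), class = "solve_result"))
  }
  w <- reconstruct_w(nlp, theta, pt)
  mult <- recover_multipliers(nlp, w, pt)
  structure(list(
    w_star = w,
    theta_star = stats::setNames(theta, names(nlp$theta_idx)),
    lambda = mult$lambda, nu = mult$nu,
    objective = evaluate_objective(nlp, w),
    status = status, iterations = res$iterations,
    message = res$message,
    constraint_violation = mult$constraint_violation,
    stationarity = mult$stationarity),
    class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("solve_result: status %s, objective %.6g, %d iterations\n",
              x$status, x$objective, x$iterations))
  invisible(x)
}

reconstruct_w <- function(nlp, theta, pt) {
  w <- numeric(nlp$n_vars)
  w[seq_len(nlp$n_theta)] <- theta
  for (k in seq_along(nlp$exps))
    w[t(nlp$exps[[k]]$var_idx)] <- t(pt$props[[k]]$states)
  if (!is.null(nlp$l1_pos)) {
    dev <- theta - rep_len(nlp$prior$mean, nlp$n_theta)
    w[nlp$l1_pos] <- pmax(dev, 0)
    w[nlp$l1_neg] <- pmax(-dev, 0)
  }
  if (!is.null(nlp$gamma_idx)) {
    cp <- cvar_objective_value(pt$e, nlp$cvar$beta)
    w[nlp$gamma_idx] <- cp$minimized$gamma
    w[nlp$slack_idx] <- pmax(pt$e - cp$minimized$gamma, 0)
  }
  w
}

## equality multipliers by per-experiment adjoint solve; bound
## multipliers from the stationarity identity nu = grad Phi + J^T lambda
recover_multipliers <- function(nlp, w, pt) {
  der <- evaluate_derivatives(nlp, w)
  lambda <- numeric(nlp$n_cons)
  if (!is.null(nlp$cvar_con)) {
    act <- pt$e > w[nlp$gamma_idx] + 1e-12
    lambda[nlp$cvar_con[act]] <- -1 / (1 - nlp$cvar$beta)
  }
  if (!is.null(nlp$l1_con)) {
    dev <- w[seq_len(nlp$n_theta)] - rep_len(nlp$prior$mean, nlp$n_theta)
    lambda[nlp$l1_con] <- ifelse(dev > 0, 1, -1) / nlp$prior$sd
  }
  for (ex in nlp$exps) {
    rows <- as.vector(t(ex$con_idx))
    cols <- as.vector(t(ex$var_idx))
    rhs <- der$gradient[cols]
    if (!is.null(nlp$cvar_con)) {
      extra <- nlp$cvar_con[lambda[nlp$cvar_con] != 0]
      if (length(extra))
        rhs <- rhs + as.vector(Matrix::crossprod(
          der$jacobian[extra, cols, drop = FALSE],
          lambda[extra]))
    }
    Jx <- der$jacobian[rows, cols, drop = FALSE]
    lam <- tryCatch(
      as.vector(Matrix::solve(Matrix::t(Jx), -rhs)),
      error = function(e) rep(NA_real_, length(rows)))
    lambda[rows] <- lam
  }
  nu <- der$gradient + as.vector(Matrix::crossprod(der$jacobian, lambda))
  cons <- evaluate_constraints(nlp, w)
  viol <- cons
  if (!is.null(nlp$cvar_con))
    viol[nlp$cvar_con] <- pmin(cons[nlp$cvar_con], 0)
  # stationarity residual on variables away from their bounds
  interior <- (w - nlp$lb > 1e-7) & (nlp$ub - w > 1e-7)
  list(lambda = lambda, nu = nu,
       constraint_violation = max(abs(viol)),
       stationarity = if (any(interior)) max(abs(nu[interior])) else 0)
}

#' Multi-start solve
#'
#' The first start is the [default_initialization()]; additional starts
#' draw the parameter vector uniformly within the (finite part of the)
#' bounds box.  Returns the lowest-objective optimal result together
#' with all individual results.
#'
#' @param nlp a `glv_nlp`.
#' @param n_starts number of starts (>= 1).
#' @param seed integer seed for the random starts.
#' @param options [solver_options()].
#' @return list with `best` (a `solve_result`) and `results`.
#' @export
multistart <- function(nlp, n_starts, seed, options = solver_options()) {
  if (n_starts < 1) stopf("'n_starts' must be >= 1")
  p <- nlp$n_theta
  lb <- nlp$lb[seq_len(p)]; ub <- nlp$ub[seq_len(p)]
  lo <- ifelse(is.finite(lb), lb, pmin(ub, 0) - 10)
  hi <- ifelse(is.finite(ub), ub, pmax(lb, 0) + 10)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1L) NULL
      else lo + stats::runif(p) * (hi - lo)
    })
  })
  results <- lapply(starts, function(s) solve_nlp(nlp, s, options))
  ok <- vapply(results, function(r) r$status == "optimal", logical(1))
  if (!any(ok))
    stopf("all %d starts failed to reach an optimal status", n_starts)
  objs <- vapply(results, function(r)
    if (r$status == "optimal") r$objective else Inf, numeric(1))
  list(best = results[[which.min(objs)]], results = results,
       objectives = objs)
}

#' Package a solved result as a warm start
#'
#' @param result an optimal `solve_result`.
#' @return a `glv_warm_start` carrying primal and dual values.
#' @export
warm_start_from <- function(result) {
  if (!identical(result$status, "optimal"))
    stopf("warm starts require an optimal result")
  structure(list(w = result$w_star, lambda = result$lambda,
                 nu = result$nu),
            class = "glv_warm_start")
}

#' Maximum a posteriori estimation of community parameters
#'
#' High-level wrapper: builds the grids, transcribes the MAP problem and
#' solves it.
#'
#' @param design an [build_design()] design.
#' @param data measurement data frame.
#' @param model_form `"glv"` or `"saturable"`.
#' @param prior a [prior_spec()].
#' @param cvar optional [cvar_spec()].
#' @param bounds optional `parameter_bounds`.
#' @param grids optional grids list.
#' @param options [solver_options()].
#' @param initial_point optional start (see [solve_nlp()]).
#' @param n_starts number of starts (uses [multistart()] when > 1).
#' @return a `glv_fit`: list with `theta` (named estimates), `result`,
#'   `nlp`, `objective`, `status`, `iterations`.
#' @export
map_estimate <- function(design, data, model_form = c("glv", "saturable"),
                         prior = prior_spec("L2"), cvar = NULL,
                         bounds = NULL, grids = NULL,
                         options = solver_options(),
                         initial_point = NULL, n_starts = 1L) {
  model_form <- match.arg(model_form)
  nlp <- transcribe(model_form, design, data, prior = prior, cvar = cvar,
                    bounds = bounds, grids = grids)
  result <- if (n_starts > 1L)
    multistart(nlp, n_starts, seed = 1L, options = options)$best
  else solve_nlp(nlp, initial_point, options)
  structure(list(theta = result$theta_star, result = result, nlp = nlp,
                 objective = result$objective, status = result$status,
                 iterations = result$iterations,
                 design = design, data = data, model_form = model_form,
                 prior = nlp$prior, cvar = nlp$cvar),
            class = "glv_fit")
}

#' @export
print.glv_fit <- function(x, ...) {
  cat(sprintf("MAP fit (%s): status %s, objective %.6g, %d parameters\n",
              x$model_form, x$status, x$objective, length(x$theta)))
  invisible(x)
}

#' @export
coef.glv_fit <- function(object, ...) object$theta
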