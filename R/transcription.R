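#' Prior specification for the MAP objective
#'
#' `"L2"` is a Gaussian prior contributing
#' `0.5 * sum(((theta - mean)/sd)^2)`; `"L1"` is a Laplacian prior
#' contributing `sum(abs(theta - mean)/sd)` (transcribed with
#' nonnegative split variables so the full-space problem stays twice
#' continuously differentiable); `"none"` drops the prior term, as
#' required for observability testing.
#'
#' @param form one of `"L2"`, `"L1"`, `"none"`.
#' @param mean prior mean per parameter (recycled; default 0).
#' @param sd prior standard deviation per parameter (recycled; default
#'   1/50).
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(form = c("L2", "L1", "none"), mean = 0, sd = 1 / 50) {
  form <- match.arg(form)
  if (form != "none" && any(sd <= 0)) stopf("prior sd must be positive")
  structure(list(form = form, mean = mean, sd = sd), class = "prior_spec")
}

expand_prior <- function(prior, n_theta) {
  list(form = prior$form,
       mean = rep_len(prior$mean, n_theta),
       sd = rep_len(prior$sd, n_theta))
}

#' CVaR (k-max) robust objective specification
#'
#' Replaces the sum of per-experiment fitting errors by
#' `K * (gamma + (1/((1-beta) K)) * sum([e_k - gamma]+))`, whose minimum
#' over the auxiliary variable `gamma` equals `K` times the mean of the
#' `(1-beta)`-fraction largest per-experiment errors.  With `beta = 0`
#' this is exactly the standard sum of errors; as `beta -> 1` it
#' penalizes only the worst experiment.
#'
#' @param beta tail fraction parameter in `[0, 1)`.
#' @return a `cvar_spec` object.
#' @export
cvar_spec <- function(beta = 0.9) {
  if (beta < 0 || beta >= 1) stopf("'beta' must lie in [0, 1)")
  structure(list(enabled = TRUE, beta = beta), class = "cvar_spec")
}

#' Biologically feasible parameter bounds
#'
#' Default box: `0.09 < mu_s < 2.1`, `-10 < alpha_{ss'} < 10` off the
#' diagonal, `-10 < alpha_{ss} < 0` on the diagonal (self-limitation),
#' and `K_{ss'} > 0` for the saturable form.
#'
#' @param species_labels community species labels.
#' @param model_form `"glv"` or `"saturable"`.
#' @param mu_range growth-rate bounds.
#' @param alpha_range cross-interaction bounds.
#' @param alpha_diag_range self-interaction bounds.
#' @param K_range saturation-constant bounds.
#' @return a `parameter_bounds` object: list with named `lower` and
#'   `upper` vectors over the packed parameter vector.
#' @export
default_parameter_bounds <- function(species_labels,
                                     model_form = c("glv", "saturable"),
                                     mu_range = c(0.09, 2.1),
                                     alpha_range = c(-10, 10),
                                     alpha_diag_range = c(-10, 0),
                                     K_range = c(1e-6, Inf)) {
  model_form <- match.arg(model_form)
  s <- length(species_labels)
  lower <- numeric(0); upper <- numeric(0)
  for (i in seq_len(s)) {
    lo <- c(mu_range[1], ifelse(seq_len(s) == i, alpha_diag_range[1],
                                alpha_range[1]))
    hi <- c(mu_range[2], ifelse(seq_len(s) == i, alpha_diag_range[2],
                                alpha_range[2]))
    lower <- c(lower, lo); upper <- c(upper, hi)
  }
  if (model_form == "saturable") {
    lower <- c(lower, rep(K_range[1], s^2))
    upper <- c(upper, rep(K_range[2], s^2))
  }
  nm <- names(theta_pack(community_parameters(
    species_labels, rep(1, s), matrix(0, s, s),
    if (model_form == "saturable") matrix(1, s, s) else NULL)))
  if (any(lower >= upper)) stopf("lower bounds must be below upper bounds")
  structure(list(lower = stats::setNames(lower, nm),
                 upper = stats::setNames(upper, nm)),
            class = "parameter_bounds")
}

## ------------------------------------------------------------------
## problem core: experiment-wise bookkeeping shared by the transcribed
## full-space problem and the reduced-space solver
## ------------------------------------------------------------------
build_core <- function(design, data, model_form, grids) {
  validate_measurements(data)
  S <- length(design$species_labels)
  n_theta <- n_parameters(S, model_form)
  theta_names <- names(default_parameter_bounds(design$species_labels,
                                                model_form)$lower)
  exps <- lapply(design$experiments, function(ex) {
    grid <- grids[[ex$experiment_id]]
    if (is.null(grid))
      stopf("no grid supplied for experiment '%s'", ex$experiment_id)
    gm <- match(ex$member_species, design$species_labels)
    rec <- data[data$experiment_id == ex$experiment_id, , drop = FALSE]
    sp <- match(rec$species, ex$member_species)
    if (anyNA(sp))
      stopf("measurements of experiment '%s' include non-member species",
            ex$experiment_id)
    ti <- match(round(rec$time_h, 10), round(grid$sample_times, 10))
    if (anyNA(ti))
      stopf("measurement time %.4f h of experiment '%s' is not a sampling time on the grid",
            rec$time_h[which(is.na(ti))[1L]], ex$experiment_id)
    list(id = ex$experiment_id, members = ex$member_species, gm = gm,
         lmap = local_theta_map(gm, S, model_form),
         n = length(gm), grid = grid, x0 = ex$initial_abundances,
         obs = data.frame(node = grid$sample_node[ti], sp = sp,
                          eta = rec$abundance, sigma = rec$std))
  })
  list(model_form = model_form, S = S,
       species_labels = design$species_labels,
       n_theta = n_theta, theta_names = theta_names, exps = exps)
}

## ------------------------------------------------------------------
## transcription to the full-space NLP
## ------------------------------------------------------------------

#' Transcribe a MAP estimation problem into a sparse NLP
#'
#' Converts the dynamic estimation problem into a fully algebraic
#' constrained optimization problem by implicit Euler discretization.
#' The variable vector `w` stacks the global parameters, any prior/CVaR
#' auxiliaries, and the discretized states of every experiment; the
#' constraints are the initial conditions, the implicit Euler step
#' equations, the dilution jumps, and (when present) the L1 split links
#' and CVaR slack inequalities.  The returned object exposes the
#' standard NLP callback contract — objective, gradient, constraints,
#' sparse Jacobian, sparse Hessian of the Lagrangian, variable and
#' constraint bounds — via [evaluate_objective()],
#' [evaluate_constraints()] and [evaluate_derivatives()].
#'
#' @param model_form `"glv"` or `"saturable"`.
#' @param design an [build_design()] design.
#' @param data measurement data frame.
#' @param prior a [prior_spec()].
#' @param cvar optional [cvar_spec()].
#' @param bounds a `parameter_bounds` object (defaults to the biological
#'   box).
#' @param grids named list of grids from [build_grids()].
#' @param params_template optional [community_parameters()] used only
#'   for species labels (design labels are used when absent).
#' @return an object of class `glv_nlp`.
#' @export
transcribe <- function(model_form = c("glv", "saturable"), design, data,
                       prior = prior_spec("L2"), cvar = NULL,
                       bounds = NULL, grids = NULL,
                       params_template = NULL) {
  model_form <- match.arg(model_form)
  if (is.null(grids)) grids <- build_grids(design)
  if (is.null(bounds))
    bounds <- default_parameter_bounds(design$species_labels, model_form)
  core <- build_core(design, data, model_form, grids)
  p <- core$n_theta
  prior_x <- expand_prior(prior, p)
  if (length(bounds$lower) != p)
    stopf("bounds cover %d parameters but the model has %d",
          length(bounds$lower), p)
  if (any(bounds$lower >= bounds$upper))
    stopf("contradictory parameter bounds (lower >= upper)")
  use_cvar <- !is.null(cvar) && isTRUE(cvar$enabled)
  use_l1 <- identical(prior_x$form, "L1")

  # variable layout
  nv <- p
  l1_pos <- l1_neg <- NULL
  if (use_l1) { l1_pos <- nv + seq_len(p); nv <- nv + p
                l1_neg <- nv + seq_len(p); nv <- nv + p }
  gamma_idx <- NULL
  if (use_cvar) { gamma_idx <- nv + 1L; nv <- nv + 1L }
  exps <- core$exps
  for (k in seq_along(exps)) {
    J <- length(exps[[k]]$grid$times); n <- exps[[k]]$n
    exps[[k]]$var_idx <- matrix(nv + seq_len(J * n), J, n, byrow = TRUE)
    nv <- nv + J * n
  }
  slack_idx <- NULL
  if (use_cvar) { slack_idx <- nv + seq_along(exps); nv <- nv + length(exps) }

  # constraint layout: per-experiment dynamics, then L1 links, then CVaR
  nc <- 0L
  for (k in seq_along(exps)) {
    J <- length(exps[[k]]$grid$times); n <- exps[[k]]$n
    exps[[k]]$con_idx <- matrix(nc + seq_len(J * n), J, n, byrow = TRUE)
    nc <- nc + J * n
  }
  l1_con <- NULL
  if (use_l1) { l1_con <- nc + seq_len(p); nc <- nc + p }
  cvar_con <- NULL
  if (use_cvar) { cvar_con <- nc + seq_along(exps); nc <- nc + length(exps) }

  lb <- rep(0, nv); ub <- rep(Inf, nv)
  lb[seq_len(p)] <- bounds$lower; ub[seq_len(p)] <- bounds$upper
  if (use_cvar) { lb[gamma_idx] <- -Inf }
  cl <- rep(0, nc); cu <- rep(0, nc)
  if (use_cvar) cu[cvar_con] <- Inf

  for (k in seq_along(exps))
    exps[[k]]$obs$var <- exps[[k]]$var_idx[
      cbind(exps[[k]]$obs$node, exps[[k]]$obs$sp)]

  structure(
    list(model_form = model_form, core = core, exps = exps,
         design = design, data = data,
         prior = prior_x, cvar = if (use_cvar) cvar else NULL,
         bounds = bounds, grids = grids,
         n_vars = nv, n_cons = nc, n_theta = p,
         theta_idx = stats::setNames(seq_len(p), core$theta_names),
         l1_pos = l1_pos, l1_neg = l1_neg, l1_con = l1_con,
         gamma_idx = gamma_idx, slack_idx = slack_idx,
         cvar_con = cvar_con,
         lb = lb, ub = ub, cl = cl, cu = cu,
         plain = !use_cvar && !use_l1),
    class = "glv_nlp")
}

#' @export
print.glv_nlp <- function(x, ...) {
  cat(sprintf(
    "Transcribed NLP (%s): %d variables, %d constraints, %d parameters, %d experiments\n",
    x$model_form, x$n_vars, x$n_cons, x$n_theta, length(x$exps)))
  invisible(x)
}

check_w <- function(nlp, w) {
  if (length(w) != nlp$n_vars)
    stopf("'w' must have length %d", nlp$n_vars)
  if (any(!is.finite(w)))
    stopf("non-finite value at variable index %d", which(!is.finite(w))[1L])
  w
}

exp_errors <- function(nlp, w) {
  vapply(nlp$exps, function(ex)
    sum(0.5 * ((ex$obs$eta - w[ex$obs$var]) / ex$obs$sigma)^2), numeric(1))
}

#' Evaluate the transcribed objective
#'
#' @param nlp a `glv_nlp` from [transcribe()].
#' @param w full variable vector.
#' @return scalar objective value.
#' @export
evaluate_objective <- function(nlp, w) {
  w <- check_w(nlp, w)
  p <- nlp$n_theta
  theta <- w[seq_len(p)]
  pr <- nlp$prior
  phi <- switch(pr$form,
    none = 0,
    L2 = 0.5 * sum(((theta - pr$mean) / pr$sd)^2),
    L1 = sum((w[nlp$l1_pos] + w[nlp$l1_neg]) / pr$sd))
  if (is.null(nlp$cvar)) {
    phi + sum(exp_errors(nlp, w))
  } else {
    K <- length(nlp$exps)
    phi + K * w[nlp$gamma_idx] +
      (1 / (1 - nlp$cvar$beta)) * sum(w[nlp$slack_idx])
  }
}

#' Evaluate the transcribed constraints
#'
#' Equality rows have both bounds zero; CVaR slack rows are one-sided
#' (`>= 0`).
#'
#' @inheritParams evaluate_objective
#' @return numeric residual vector of length `nlp$n_cons`.
#' @export
evaluate_constraints <- function(nlp, w) {
  w <- check_w(nlp, w)
  out <- numeric(nlp$n_cons)
  theta <- w[seq_len(nlp$n_theta)]
  for (ex in nlp$exps) {
    lp <- local_lp(theta[ex$lmap], ex$n, nlp$model_form)
    grid <- ex$grid
    x <- matrix(w[t(ex$var_idx)], ncol = ex$n, byrow = TRUE)
    out[ex$con_idx[1L, ]] <- x[1L, ] - ex$x0
    for (j in 2:length(grid$times)) {
      if (grid$kind[j] == "dilution") {
        out[ex$con_idx[j, ]] <- x[j, ] - grid$dilution_factor * x[j - 1L, ]
      } else {
        h <- grid$times[j] - grid$times[j - 1L]
        out[ex$con_idx[j, ]] <-
          x[j, ] - x[j - 1L, ] - h * model_f(x[j, ], lp, nlp$model_form)
      }
    }
  }
  if (!is.null(nlp$l1_con)) {
    pr <- nlp$prior
    out[nlp$l1_con] <- theta - pr$mean - w[nlp$l1_pos] + w[nlp$l1_neg]
  }
  if (!is.null(nlp$cvar_con))
    out[nlp$cvar_con] <- w[nlp$slack_idx] + w[nlp$gamma_idx] -
      exp_errors(nlp, w)
  out
}

#' Evaluate exact first and second derivatives of the transcribed NLP
#'
#' Returns the analytic objective gradient, the sparse constraint
#' Jacobian, and the sparse Hessian of the Lagrangian
#' `obj_factor * Phi(w) + sum(multipliers * Pi(w))`.
#'
#' @inheritParams evaluate_objective
#' @param multipliers equality/inequality multipliers (length
#'   `nlp$n_cons`; defaults to zeros, giving the objective Hessian).
#' @param obj_factor scale on the objective part of the Lagrangian.
#' @return list with `gradient` (dense), `jacobian`
#'   (`Matrix::dgCMatrix`), `hessian` (symmetric `Matrix::dsCMatrix`).
#' @export
evaluate_derivatives <- function(nlp, w, multipliers = NULL,
                                 obj_factor = 1) {
  w <- check_w(nlp, w)
  if (is.null(multipliers)) multipliers <- numeric(nlp$n_cons)
  if (length(multipliers) != nlp$n_cons)
    stopf("'multipliers' must have length %d", nlp$n_cons)
  p <- nlp$n_theta
  theta <- w[seq_len(p)]
  pr <- nlp$prior

  grad <- numeric(nlp$n_vars)
  ji <- list(); jj <- list(); jx <- list()   # jacobian triplets
  hi <- list(); hj <- list(); hx <- list()   # hessian triplets (lower)
  pushJ <- function(i, j, v) {
    keep <- v != 0
    ji[[length(ji) + 1L]] <<- i[keep]
    jj[[length(jj) + 1L]] <<- j[keep]
    jx[[length(jx) + 1L]] <<- v[keep]
  }
  pushH <- function(i, j, v) {
    keep <- v != 0
    i <- i[keep]; j <- j[keep]; v <- v[keep]
    sw <- i < j                      # store lower triangle (i >= j)
    tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
    hi[[length(hi) + 1L]] <<- i
    hj[[length(hj) + 1L]] <<- j
    hx[[length(hx) + 1L]] <<- v
  }

  # objective gradient: prior part
  if (pr$form == "L2") {
    grad[seq_len(p)] <- obj_factor * (theta - pr$mean) / pr$sd^2
    pushH(seq_len(p), seq_len(p), rep(obj_factor, p) / pr$sd^2)
  } else if (pr$form == "L1") {
    grad[nlp$l1_pos] <- obj_factor / pr$sd
    grad[nlp$l1_neg] <- obj_factor / pr$sd
  }
  # objective gradient: likelihood / CVaR part
  if (is.null(nlp$cvar)) {
    for (ex in nlp$exps) {
      r <- (w[ex$obs$var] - ex$obs$eta) / ex$obs$sigma^2
      grad[ex$obs$var] <- grad[ex$obs$var] + obj_factor * r
      pushH(ex$obs$var, ex$obs$var, obj_factor / ex$obs$sigma^2)
    }
  } else {
    K <- length(nlp$exps)
    grad[nlp$gamma_idx] <- obj_factor * K
    grad[nlp$slack_idx] <- obj_factor / (1 - nlp$cvar$beta)
  }

  # dynamics constraints
  for (ex in nlp$exps) {
    lp <- local_lp(theta[ex$lmap], ex$n, nlp$model_form)
    grid <- ex$grid
    n <- ex$n
    x <- matrix(w[t(ex$var_idx)], ncol = n, byrow = TRUE)
    pushJ(ex$con_idx[1L, ], ex$var_idx[1L, ], rep(1, n))
    for (j in 2:length(grid$times)) {
      rows <- ex$con_idx[j, ]
      if (grid$kind[j] == "dilution") {
        pushJ(rows, ex$var_idx[j, ], rep(1, n))
        pushJ(rows, ex$var_idx[j - 1L, ],
              rep(-grid$dilution_factor, n))
        next
      }
      h <- grid$times[j] - grid$times[j - 1L]
      z <- x[j, ]
      A <- diag(n) - h * model_fx(z, lp, nlp$model_form)
      ft <- -h * model_ftheta(z, lp, nlp$model_form)
      pushJ(rep(rows, n), rep(ex$var_idx[j, ], each = n), as.vector(A))
      pushJ(rows, ex$var_idx[j - 1L, ], rep(-1, n))
      pushJ(rep(rows, length(ex$lmap)),
            rep(ex$lmap, each = n), as.vector(ft))
      lam <- multipliers[rows]
      if (any(lam != 0)) {
        Hblk <- -h * model_f2sum(z, lp, nlp$model_form, lam)
        gidx <- c(ex$var_idx[j, ], ex$lmap)
        nz <- which(Hblk != 0, arr.ind = TRUE)
        nz <- nz[nz[, 1L] >= nz[, 2L], , drop = FALSE]  # local lower tri
        if (nrow(nz))
          pushH(gidx[nz[, 1L]], gidx[nz[, 2L]], Hblk[nz])
      }
    }
  }
  # L1 split links
  if (!is.null(nlp$l1_con)) {
    pushJ(nlp$l1_con, seq_len(p), rep(1, p))
    pushJ(nlp$l1_con, nlp$l1_pos, rep(-1, p))
    pushJ(nlp$l1_con, nlp$l1_neg, rep(1, p))
  }
  # CVaR slack rows: s_k + gamma - e_k(w) >= 0
  if (!is.null(nlp$cvar_con)) {
    for (k in seq_along(nlp$exps)) {
      ex <- nlp$exps[[k]]
      row <- nlp$cvar_con[k]
      pushJ(row, nlp$slack_idx[k], 1)
      pushJ(row, nlp$gamma_idx, 1)
      de <- (w[ex$obs$var] - ex$obs$eta) / ex$obs$sigma^2
      pushJ(rep(row, nrow(ex$obs)), ex$obs$var, -de)
      lam <- multipliers[row]
      if (lam != 0)
        pushH(ex$obs$var, ex$obs$var, -lam / ex$obs$sigma^2)
    }
  }

  jac <- Matrix::sparseMatrix(i = unlist(ji), j = unlist(jj),
                              x = unlist(jx),
                              dims = c(nlp$n_cons, nlp$n_vars))
  hess <- Matrix::sparseMatrix(i = unlist(hi), j = unlist(hj),
                               x = unlist(hx), symmetric = TRUE,
                               dims = c(nlp$n_vars, nlp$n_vars))
  list(gradient = grad, jacobian = jac, hessian = hess)
}

#' CVaR objective value and its minimized form
#'
#' For per-experiment errors `e` and `beta` in `[0, 1)`, the CVaR
#' objective contribution is `K * (gamma + (1/((1-beta) K)) *
#' sum(pmax(e - gamma, 0)))`.  Its minimum over `gamma` is attained at
#' the empirical `beta`-quantile of the errors, where it equals `K`
#' times `CVaR_beta(e)`, the mean of the `(1-beta)`-fraction largest
#' errors; at `beta = 0` the minimized objective is exactly `sum(e)` and
#' as `beta -> 1` the CVaR tends to `max(e)`.
#'
#' @param errors numeric vector of per-experiment errors.
#' @param beta tail parameter in `[0, 1)`.
#' @param gamma optional threshold; when supplied the objective is also
#'   evaluated at this `gamma`.
#' @return list with `minimized` (list `gamma`, `objective`, `cvar`) and,
#'   when `gamma` was given, `objective` at that `gamma`.
#' @export
cvar_objective_value <- function(errors, beta, gamma = NULL) {
  if (beta < 0 || beta >= 1) stopf("'beta' must lie in [0, 1)")
  if (!length(errors)) stopf("'errors' must be non-empty")
  K <- length(errors)
  obj_at <- function(g)
    K * (g + sum(pmax(errors - g, 0)) / ((1 - beta) * K))
  m <- ceiling((1 - beta) * K)
  gstar <- sort(errors, decreasing = TRUE)[m]
  out <- list(minimized = list(gamma = gstar, objective = obj_at(gstar),
                               cvar = obj_at(gstar) / K))
  if (!is.null(gamma)) out$objective <- obj_at(gamma)
  out
}

#' Discretization sufficiency check
#'
#' Re-estimates the parameters on a grid refined by `factor` and applies
#' the per-parameter criterion: a parameter passes if the absolute
#' change is below `eps_abs` or the relative change is below `eps_rel`
#' (absolute values on both tests).
#'
#' @param estimate_fn function taking a grids list and returning a named
#'   parameter vector (e.g. a wrapper around [map_estimate()]).
#' @param grids grids list of the base discretization.
#' @param eps_abs,eps_rel thresholds (default 0.01).
#' @param factor refinement factor (default 2).
#' @return a `discretization_check` object with per-parameter deltas,
#'   pass flags, the overall `verdict`, and the worst offender.
#' @export
check_discretization <- function(estimate_fn, grids, eps_abs = 0.01,
                                 eps_rel = 0.01, factor = 2) {
  theta <- estimate_fn(grids)
  theta_ref <- estimate_fn(refine_grids(grids, factor))
  ad <- abs(theta - theta_ref)
  rd <- ad / abs(theta)
  pass <- (ad < eps_abs) | (rd < eps_rel)
  worst <- which.max(pmin(ad / eps_abs, rd / eps_rel))
  structure(list(theta = theta, theta_refined = theta_ref,
                 abs_diff = ad, rel_diff = rd, pass = pass,
                 eps_abs = eps_abs, eps_rel = eps_rel,
                 verdict = all(pass),
                 worst = names(theta)[worst] %||% worst),
            class = "discretization_check")
}

#' @export
print.discretization_check <- function(x, ...) {
  cat(sprintf("Discretization check: %s (%d/%d parameters pass; worst: %s)\n",
              if (x$verdict) "PASS" else "FAIL",
              sum(x$pass), length(x$pass), x$worst))
  invisible(x)
}
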