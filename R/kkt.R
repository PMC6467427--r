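#' Inertia of a symmetric matrix via LBL^T factorization
#'
#' Counts positive, negative and zero eigenvalues from the 1x1/2x2
#' diagonal blocks of a symmetric-indefinite (Bunch-Kaufman)
#' factorization, without an eigendecomposition.  A block eigenvalue is
#' declared zero when its magnitude is below `tol` times the largest
#' block-eigenvalue magnitude.
#'
#' @param M symmetric matrix (base or Matrix; coerced to dense).
#' @param tol relative zero threshold (default 1e-8).
#' @param equilibrate symmetrically scale rows/columns to unit infinity
#'   norm before factorizing (default TRUE).  The congruence preserves
#'   the inertia (Sylvester's law) while making the relative zero
#'   threshold meaningful for badly scaled saddle-point matrices, whose
#'   large Hessian entries otherwise pair huge positive with tiny
#'   negative eigenvalues.
#' @return named integer vector `c(n_plus, n_minus, n_zero)`.
#' @export
inertia <- function(M, tol = 1e-8, equilibrate = TRUE) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stopf("matrix must be square")
  if (nrow(M) && max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stopf("matrix must be symmetric")
  M <- (M + t(M)) / 2
  if (equilibrate && nrow(M)) {
    d <- sqrt(pmax(apply(abs(M), 1L, max), 1e-300))
    M <- M / d / rep(d, each = nrow(M))
  }
  storage.mode(M) <- "double"
  out <- .Call(C_ldl_inertia, M, as.numeric(tol))
  stats::setNames(out, c("n_plus", "n_minus", "n_zero"))
}

#' Assemble the augmented KKT matrix at a solution
#'
#' Builds the symmetric saddle-point matrix
#' `M(kappa_w) = [[H + kappa_w I, J'], [J, 0]]` with `H` the exact
#' Hessian of the Lagrangian at `(w*, lambda*)` (plus the primal barrier
#' curvature of the bounds when `mu_b > 0`), and reports the KKT
#' residuals of the stationarity, feasibility and complementarity
#' conditions.
#'
#' @param nlp a plain (no CVaR, no L1 split) `glv_nlp`.
#' @param result an optimal [solve_nlp()] result carrying multipliers.
#' @param kappa_w Hessian regularization (default 0).
#' @param mu_b barrier value for the bound curvature term (default 0:
#'   inactive-bound terms are dropped, as appropriate for the pure
#'   observability test).
#' @return a `glv_kkt` object: `M`, `H`, `J`, dimensions `n`, `m`,
#'   multipliers and residuals.
#' @export
assemble_kkt <- function(nlp, result, kappa_w = 0, mu_b = 0) {
  if (!isTRUE(nlp$plain))
    stopf("KKT analysis requires a plain transcription (no CVaR/L1 auxiliaries)")
  if (is.null(result$lambda) || is.null(result$nu))
    stopf("result carries no multipliers")
  w <- result$w_star
  der <- evaluate_derivatives(nlp, w, result$lambda)
  H <- der$hessian
  if (mu_b > 0) {
    dl <- w - nlp$lb; du <- nlp$ub - w
    bar <- ifelse(is.finite(nlp$lb), mu_b / pmax(dl, 1e-12)^2, 0) +
      ifelse(is.finite(nlp$ub), mu_b / pmax(du, 1e-12)^2, 0)
    H <- H + Matrix::Diagonal(nlp$n_vars, bar)
  }
  if (kappa_w != 0)
    H <- H + Matrix::Diagonal(nlp$n_vars, kappa_w)
  J <- der$jacobian
  M <- rbind(cbind(H, Matrix::t(J)),
             cbind(J, Matrix::Matrix(0, nlp$n_cons, nlp$n_cons,
                                     sparse = TRUE)))
  stat <- der$gradient +
    as.vector(Matrix::crossprod(J, result$lambda)) - result$nu
  structure(list(M = Matrix::forceSymmetric(M, uplo = "L"),
                 H = H, J = J,
                 n = nlp$n_vars, m = nlp$n_cons,
                 kappa_w = kappa_w, mu_b = mu_b,
                 w = w, lambda = result$lambda, nu = result$nu,
                 residuals = list(
                   stationarity = max(abs(stat)),
                   primal = max(abs(evaluate_constraints(nlp, w)))),
                 nlp = nlp),
            class = "glv_kkt")
}

#' Block-bordered-diagonal (arrowhead) view of a KKT system
#'
#' The parameters are the only variables shared across experiments, so
#' ordering the augmented matrix as (theta | x_1, lambda_1 | ... | x_K,
#' lambda_K) yields a block-bordered-diagonal matrix: a parameter block
#' `K_theta`, per-experiment saddle blocks `K_k = [[H_k, J_k'], [J_k,
#' 0]]`, and borders `B_k = [Q_k, T_k']` built from the mixed
#' parameter-state Hessian and the parameter Jacobian.
#' `split_bbd()` extracts this structure from an assembled KKT system;
#' `bbd_system()` builds one directly from matrices (useful for
#' constructed test instances).
#'
#' @param kkt a `glv_kkt` from [assemble_kkt()].
#' @return a `glv_bbd` object: `K_theta`, `blocks` (each with `K`, `B`,
#'   `n_k`, `m_k`), `n_theta`, and the permutation `perm` with
#'   `M_bbd = M[perm, perm]`.
#' @export
split_bbd <- function(kkt) {
  nlp <- kkt$nlp
  p <- nlp$n_theta
  H <- methods::as(kkt$H, "generalMatrix")   # sparse, both triangles
  J <- kkt$J
  ti <- seq_len(p)
  blocks <- list(); perm <- ti
  for (ex in nlp$exps) {
    v <- as.vector(t(ex$var_idx))
    cc <- as.vector(t(ex$con_idx))
    Hk <- H[v, v, drop = FALSE]
    Jk <- J[cc, v, drop = FALSE]
    Kk <- rbind(cbind(Hk, Matrix::t(Jk)),
                cbind(Jk, Matrix::Matrix(0, length(cc), length(cc),
                                         sparse = TRUE)))
    Qk <- H[ti, v, drop = FALSE]
    Tk <- J[cc, ti, drop = FALSE]
    blocks[[length(blocks) + 1L]] <-
      list(id = ex$id, K = Kk,
           B = as.matrix(cbind(Qk, Matrix::t(Tk))),
           n_k = length(v), m_k = length(cc))
    perm <- c(perm, v, kkt$n + cc)
  }
  bbd_system(as.matrix(H[ti, ti, drop = FALSE]), blocks, perm = perm)
}

#' @rdname split_bbd
#' @param K_theta dense parameter block (n_theta x n_theta).
#' @param blocks list of blocks, each a list with `K` (square saddle
#'   block) and `B` (n_theta x dim(K) border), optionally `n_k`, `m_k`.
#' @param perm optional permutation relating the BBD ordering to an
#'   assembled augmented matrix.
#' @export
bbd_system <- function(K_theta, blocks, perm = NULL) {
  K_theta <- as.matrix(K_theta)
  p <- nrow(K_theta)
  for (b in blocks) {
    if (nrow(b$B) != p || ncol(b$B) != nrow(b$K))
      stopf("border block dimensions are inconsistent")
  }
  blocks <- lapply(blocks, function(b) {
    if (is.null(b$n_k)) {
      b$m_k <- (nrow(b$K)) %/% 2L
      b$n_k <- nrow(b$K) - b$m_k
    }
    b$n_k <- as.integer(b$n_k); b$m_k <- as.integer(b$m_k)
    b
  })
  structure(list(K_theta = K_theta, blocks = blocks, n_theta = p,
                 perm = perm),
            class = "glv_bbd")
}

#' Assemble the full matrix of a BBD system (dense)
#'
#' @param bbd a `glv_bbd`.
#' @return dense symmetric matrix in BBD ordering.
#' @export
bbd_matrix <- function(bbd) {
  p <- bbd$n_theta
  sizes <- vapply(bbd$blocks, function(b) nrow(b$K), integer(1))
  N <- p + sum(sizes)
  M <- matrix(0, N, N)
  M[seq_len(p), seq_len(p)] <- bbd$K_theta
  off <- p
  for (b in bbd$blocks) {
    idx <- off + seq_len(nrow(b$K))
    M[idx, idx] <- as.matrix(b$K)
    M[seq_len(p), idx] <- as.matrix(b$B)
    M[idx, seq_len(p)] <- t(as.matrix(b$B))
    off <- off + nrow(b$K)
  }
  M
}

schur_complement <- function(bbd) {
  S <- bbd$K_theta
  solves <- vector("list", length(bbd$blocks))
  for (k in seq_along(bbd$blocks)) {
    b <- bbd$blocks[[k]]
    KiB <- tryCatch(as.matrix(solve(b$K, t(as.matrix(b$B)))),
                    error = function(e)
                      stopf("experiment block %s is singular",
                            b$id %||% as.character(k)))
    S <- S - as.matrix(b$B) %*% KiB
    solves[[k]] <- KiB
  }
  list(S = as.matrix(S), KiB = solves)
}

#' Solve a BBD system by Schur complement elimination
#'
#' Forms the parameter-space Schur complement
#' `S = K_theta - sum_k B_k K_k^{-1} B_k'`, solves for the parameter
#' step, and back-substitutes independently per experiment block.
#'
#' @param bbd a `glv_bbd`.
#' @param rhs right-hand side: either a full vector in BBD ordering or a
#'   list `list(r_theta = ..., r_k = list(...))`.
#' @return list with `theta` (parameter part), `blocks` (per-block
#'   parts), `x` (full solution vector) and the Schur matrix `S`.
#' @export
schur_solve <- function(bbd, rhs) {
  p <- bbd$n_theta
  sizes <- vapply(bbd$blocks, function(b) nrow(b$K), integer(1))
  if (is.list(rhs)) {
    r_theta <- rhs$r_theta
    r_k <- rhs$r_k
  } else {
    r_theta <- rhs[seq_len(p)]
    off <- p
    r_k <- lapply(sizes, function(s) {
      out <- rhs[off + seq_len(s)]; off <<- off + s; out
    })
  }
  sc <- schur_complement(bbd)
  acc <- r_theta
  Kir <- vector("list", length(bbd$blocks))
  for (k in seq_along(bbd$blocks)) {
    b <- bbd$blocks[[k]]
    Kir[[k]] <- solve(b$K, r_k[[k]])
    acc <- acc - as.vector(b$B %*% Kir[[k]])
  }
  dtheta <- tryCatch(solve(sc$S, acc), error = function(e)
    stopf("Schur complement is singular: the parameters are not observable from this system"))
  xb <- lapply(seq_along(bbd$blocks), function(k)
    as.vector(Kir[[k]] - sc$KiB[[k]] %*% dtheta))
  list(theta = as.vector(dtheta), blocks = xb,
       x = c(as.vector(dtheta), unlist(xb)), S = sc$S)
}

#' Inertia of a BBD system via Haynsworth additivity
#'
#' The inertia of the full matrix equals the sum of the per-block
#' inertias plus the inertia of the Schur complement.  The parameters
#' are locally unique (observable) exactly when every block has inertia
#' `(n_k, m_k, 0)` and the Schur complement — the reduced Hessian — is
#' positive definite.
#'
#' @param bbd a `glv_bbd`.
#' @param tol relative zero-pivot threshold for [inertia()].
#' @return an `inertia_report`: totals, per-block inertias,
#'   `schur_inertia`, the Schur matrix `S`, the expected inertia, and a
#'   `verdict` (`"observable"`, `"not_observable"`, or
#'   `"rank_deficient_jacobian"`).
#' @export
bbd_inertia <- function(bbd, tol = 1e-8) {
  sc <- schur_complement(bbd)
  binert <- lapply(bbd$blocks, function(b) inertia(b$K, tol))
  sinert <- inertia(sc$S, tol)
  tot <- Reduce(`+`, binert, accumulate = FALSE) + sinert
  blocks_ok <- all(vapply(seq_along(bbd$blocks), function(k) {
    b <- bbd$blocks[[k]]
    all(binert[[k]] == c(b$n_k, b$m_k, 0L))
  }, logical(1)))
  blocks_singular <- any(vapply(binert, function(bi)
    bi[["n_zero"]] > 0L, logical(1)))
  verdict <- if (blocks_singular) "rank_deficient_jacobian"
  else if (!blocks_ok) "not_observable"
  else if (all(sinert == c(bbd$n_theta, 0L, 0L))) "observable"
  else "not_observable"
  n <- bbd$n_theta + sum(vapply(bbd$blocks, function(b) b$n_k, integer(1)))
  m <- sum(vapply(bbd$blocks, function(b) b$m_k, integer(1)))
  structure(list(n_plus = tot[["n_plus"]], n_minus = tot[["n_minus"]],
                 n_zero = tot[["n_zero"]],
                 expected = c(n_plus = n, n_minus = m, n_zero = 0L),
                 block_inertia = binert, schur_inertia = sinert,
                 S = sc$S, verdict = verdict),
            class = "inertia_report")
}

#' @export
print.inertia_report <- function(x, ...) {
  cat(sprintf("Inertia (%d, %d, %d); expected (%d, %d, %d); verdict: %s\n",
              x$n_plus, x$n_minus, x$n_zero, x$expected[1], x$expected[2],
              x$expected[3], x$verdict))
  invisible(x)
}

#' Observability test and covariance approximation
#'
#' Assembles the augmented KKT matrix at the solution with
#' `kappa_w = 0`, splits it into BBD form and computes the inertia
#' verdict via Haynsworth's formula.  When the parameters are
#' observable, the inverse of the Schur complement (the reduced
#' Hessian) is returned as the approximate parameter covariance.  For a
#' pure uniqueness test the problem should be transcribed without a
#' prior; analysing a problem with an L2 prior answers the different
#' question of posterior uniqueness (the prior adds its inverse
#' covariance to the reduced Hessian).
#'
#' @param nlp a plain `glv_nlp`.
#' @param result an optimal [solve_nlp()] result.
#' @param tol zero-pivot threshold.
#' @return list with `report` (the `inertia_report`), `covariance`
#'   (named matrix or NULL), and `active_bounds` (indices of variables
#'   at their bounds, which degrade the covariance approximation).
#' @export
observability_test <- function(nlp, result, tol = 1e-8) {
  if (!identical(result$status, "optimal"))
    stopf("observability requires an optimal result")
  kkt <- assemble_kkt(nlp, result, kappa_w = 0, mu_b = 0)
  bbd <- split_bbd(kkt)
  report <- bbd_inertia(bbd, tol)
  covariance <- NULL
  if (report$verdict == "observable") {
    covariance <- solve(report$S)
    dimnames(covariance) <- list(names(nlp$theta_idx),
                                 names(nlp$theta_idx))
  }
  w <- result$w_star
  active <- which((w - nlp$lb < 1e-7) | (nlp$ub - w < 1e-7))
  list(report = report, covariance = covariance, active_bounds = active)
}

#' Export a sparse symmetric matrix in coordinate text format
#'
#' @param M matrix (base or Matrix).
#' @param path output file; columns `i`, `j`, `value` (lower triangle).
#' @return invisibly, `path`.
#' @export
write_coordinate <- function(M, path) {
  M <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  keep <- M@i >= M@j
  utils::write.csv(data.frame(i = M@i[keep] + 1L, j = M@j[keep] + 1L,
                              value = M@x[keep]),
                   path, row.names = FALSE)
  invisible(path)
}
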