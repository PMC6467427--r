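#' Perturbation specification for randomized-MAP sampling
#'
#' @param perturb_data perturb the observations with their own noise
#'   model, `eta + e`, `e ~ N(0, std^2)` (default TRUE; this is the
#'   sampling procedure used for the community posterior studies).
#' @param perturb_prior_mean additionally perturb the prior mean with
#'   `N(0, Sigma_theta)` draws (default FALSE; available because the
#'   Bayesian derivation's stacked data vector includes the prior mean).
#' @param seed integer seed.
#' @return a `perturbation_spec` object.
#' @export
perturbation_spec <- function(perturb_data = TRUE,
                              perturb_prior_mean = FALSE, seed = 1L) {
  if (!perturb_data && !perturb_prior_mean)
    stopf("at least one perturbation must be enabled")
  structure(list(perturb_data = perturb_data,
                 perturb_prior_mean = perturb_prior_mean,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Randomized-MAP posterior sampling
#'
#' Draws approximate samples from the parameter posterior by repeatedly
#' perturbing the data with its own noise distribution and re-solving
#' the MAP problem, warm-started from the unperturbed solution.  The
#' sample distribution is exact to second order: for linear
#' parameter-to-output maps without active bounds it is Gaussian with
#' mean `theta*` and covariance `(grad m' Sigma^-1 grad m)^-1`.  Unlike
#' an unconstrained Gaussian approximation, every sample respects the
#' parameter bounds.
#'
#' @param fit a `glv_fit` from [map_estimate()] (status must be
#'   optimal).
#' @param n_samples number of MAP re-solves (default 500).
#' @param spec a [perturbation_spec()].
#' @param options [solver_options()] for the re-solves.
#' @return a `posterior_samples` object: `samples` (n_samples x
#'   n_theta, failed solves as NA rows), `status`, `iterations`,
#'   `map_estimate`, `n_failed`.
#' @export
rmap_sample <- function(fit, n_samples = 500L, spec = perturbation_spec(),
                        options = solver_options()) {
  if (!identical(fit$status, "optimal"))
    stopf("rMAP sampling requires an optimal MAP fit")
  nlp <- fit$nlp
  theta_star <- unname(fit$theta)
  resolve <- function(nlp2) {
    r <- solve_nlp(nlp2, theta_star, options)
    list(theta = unname(r$theta_star), status = r$status,
         iterations = r$iterations)
  }
  sizes <- vapply(nlp$exps, function(ex) nrow(ex$obs), integer(1))
  sigma <- unlist(lapply(nlp$exps, function(ex) ex$obs$sigma))
  p <- nlp$n_theta
  out <- with_seed(spec$seed, {
    samples <- matrix(NA_real_, n_samples, p)
    status <- character(n_samples)
    iters <- integer(n_samples)
    for (b in seq_len(n_samples)) {
      nlp2 <- nlp
      if (spec$perturb_data) {
        eps <- stats::rnorm(length(sigma), sd = sigma)
        off <- 0L
        for (k in seq_along(nlp2$exps)) {
          nlp2$exps[[k]]$obs$eta <- nlp2$exps[[k]]$obs$eta +
            eps[off + seq_len(sizes[k])]
          off <- off + sizes[k]
        }
      }
      if (spec$perturb_prior_mean && nlp2$prior$form != "none")
        nlp2$prior$mean <- nlp2$prior$mean +
          stats::rnorm(p, sd = nlp2$prior$sd)
      r <- resolve(nlp2)
      status[b] <- r$status
      iters[b] <- r$iterations
      if (r$status == "optimal") samples[b, ] <- r$theta
    }
    list(samples = samples, status = status, iterations = iters)
  })
  colnames(out$samples) <- names(nlp$theta_idx)
  n_failed <- sum(out$status != "optimal")
  if (n_failed > 0.2 * n_samples)
    warning(sprintf("%d of %d rMAP sub-solves failed", n_failed,
                    n_samples))
  structure(list(samples = out$samples, status = out$status,
                 iterations = out$iterations,
                 map_estimate = fit$theta, n_failed = n_failed),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("rMAP posterior samples: %d draws (%d failed), %d parameters\n",
              nrow(x$samples), x$n_failed, ncol(x$samples)))
  invisible(x)
}

#' Moment and correlation summary of posterior samples
#'
#' Column-wise mean and (unbiased) standard deviation, Pearson
#' correlations, and the central third and fourth moments normalized by
#' `sigma^3` and `sigma^4` (skewness, and kurtosis with Gaussian
#' reference value 3).
#'
#' @param samples a `posterior_samples` object or a numeric matrix (one
#'   row per draw); rows with NA are dropped.
#' @return a `posterior_summary`: `mean`, `std`, `correlation`,
#'   `moment3`, `moment4`, `n_samples`, `zero_variance` flags.
#' @export
summarize_posterior <- function(samples) {
  X <- if (inherits(samples, "posterior_samples")) samples$samples
  else as.matrix(samples)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 2L) stopf("at least two valid samples are required")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  ctr <- sweep(X, 2L, mu)
  # population moments for skewness/kurtosis normalization
  s2 <- colMeans(ctr^2)
  m3 <- colMeans(ctr^3) / s2^1.5
  m4 <- colMeans(ctr^4) / s2^2
  zerovar <- sdv == 0 | !is.finite(m3)
  m3[zerovar] <- 0; m4[zerovar] <- 0
  cr <- suppressWarnings(stats::cor(X))
  cr[!is.finite(cr)] <- 0
  diag(cr) <- 1
  structure(list(mean = mu, std = sdv, correlation = cr,
                 moment3 = m3, moment4 = m4, n_samples = nrow(X),
                 zero_variance = zerovar),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary over %d samples, %d parameters\n",
              x$n_samples, length(x$mean)))
  invisible(x)
}

#' Pairwise confidence ellipse from a 2x2 covariance
#'
#' The level-`level` ellipse of a bivariate Gaussian is
#' `{d : d' cov^-1 d <= q}` with `q` the chi-square(2) quantile;
#' semi-axes are `sqrt(q * eigenvalues)` along the eigenvectors.
#'
#' @param cov_2x2 symmetric positive semidefinite 2x2 matrix.
#' @param level coverage level (default 0.95).
#' @return a `confidence_ellipse`: `semi_axes`, `rotation` (radians of
#'   the major axis), `axes` (eigenvector matrix), `q`, `degenerate`
#'   flag.
#' @export
confidence_ellipse <- function(cov_2x2, level = 0.95) {
  C <- as.matrix(cov_2x2)
  if (!all(dim(C) == c(2L, 2L))) stopf("covariance must be 2 x 2")
  if (max(abs(C - t(C))) > 1e-10 * max(1, max(abs(C))))
    stopf("covariance must be symmetric")
  ee <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (any(ee$values < -1e-12 * max(abs(ee$values), 1)))
    stopf("covariance must be positive semidefinite")
  ev <- pmax(ee$values, 0)
  q <- stats::qchisq(level, df = 2)
  structure(list(semi_axes = sqrt(q * ev),
                 rotation = atan2(ee$vectors[2L, 1L], ee$vectors[1L, 1L]),
                 axes = ee$vectors, q = q,
                 degenerate = any(ev <= 1e-14 * max(ev, 1))),
            class = "confidence_ellipse")
}

#' Low-level randomized-MAP engine
#'
#' Generic perturb-and-re-solve loop for problems outside the community
#' pipeline (e.g. linear-Gaussian reference problems): given
#' observations and their standard deviations, repeatedly draws
#' `eta + N(0, std^2)` and calls `resolve_fn(eta_perturbed)` which must
#' return a parameter vector.
#'
#' @param eta observation vector.
#' @param std per-observation standard deviations.
#' @param resolve_fn function of the perturbed observation vector
#'   returning a numeric parameter vector.
#' @param n_samples number of draws.
#' @param seed integer seed.
#' @return matrix of samples (n_samples x n_theta).
#' @export
rmap_draws <- function(eta, std, resolve_fn, n_samples, seed) {
  with_seed(seed, {
    first <- resolve_fn(eta + stats::rnorm(length(eta), sd = std))
    samples <- matrix(NA_real_, n_samples, length(first))
    samples[1L, ] <- first
    for (b in seq_len(n_samples)[-1L])
      samples[b, ] <- resolve_fn(eta + stats::rnorm(length(eta), sd = std))
    samples
  })
}
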