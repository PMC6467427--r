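# Shared fixtures and independent oracles.  Expensive fixtures are
# memoised for the session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# class-mean prior used in the synthetic recovery studies: generating
# distribution means with the 1/50 standard deviation
class_mean_prior <- function(S, sd = 1 / 50) {
  pm <- theta_pack(community_parameters(
    paste0("sp", seq_len(S)), rep(0.3, S), diag(-1, S)))
  prior_spec("L2", mean = pm, sd = sd)
}

fixture_small2 <- function() memo("small2", {
  des <- build_design(2)
  params <- draw_parameters(2, seed = 7)
  data <- generate_dataset(params, des, seed = 3)
  grids <- build_grids(des, mono_substeps = 1, pairwise_n_intervals = 120)
  nlp <- transcribe("glv", des, data, prior = prior_spec("L2"),
                    grids = grids)
  list(design = des, params = params, data = data, grids = grids,
       nlp = nlp)
})

fixture_fit3 <- function() memo("fit3", {
  des <- build_design(3)
  params <- draw_parameters(3, seed = 101)
  data <- generate_dataset(params, des, seed = 202)
  fit <- map_estimate(des, data, prior = class_mean_prior(3))
  list(design = des, params = params, data = data, fit = fit)
})

# central finite differences
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_jacobian <- function(f, x, h = 1e-6) {
  cols <- lapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

# dense eigendecomposition inertia oracle
eigen_inertia <- function(M, tol = 1e-8) {
  ev <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
  thr <- tol * max(abs(ev), 1e-300)
  c(sum(ev > thr), sum(ev < -thr), sum(abs(ev) <= thr))
}

random_symmetric <- function(n) {
  A <- matrix(rnorm(n * n), n)
  (A + t(A)) / 2
}

# random BBD system with saddle-structured nonsingular blocks
random_bbd <- function(p, block_sizes) {
  blocks <- lapply(block_sizes, function(sz) {
    n_k <- sz[1]; m_k <- sz[2]
    H <- random_symmetric(n_k)
    J <- matrix(rnorm(m_k * n_k), m_k, n_k) +
      cbind(diag(m_k), matrix(0, m_k, n_k - m_k))
    K <- rbind(cbind(H, t(J)), cbind(J, matrix(0, m_k, m_k)))
    list(K = K, B = matrix(rnorm(p * (n_k + m_k)), p), n_k = n_k,
         m_k = m_k)
  })
  bbd_system(random_symmetric(p) + diag(p), blocks)
}

# brute-force gamma-grid oracle for the minimized CVaR objective
cvar_brute <- function(errors, beta, n_grid = 20001) {
  K <- length(errors)
  grid <- seq(min(errors) - 1, max(errors) + 1, length.out = n_grid)
  vals <- vapply(grid, function(g)
    K * (g + sum(pmax(errors - g, 0)) / ((1 - beta) * K)), numeric(1))
  min(vals)
}

# linear-Gaussian toy for uncertainty-quantification oracles
linear_toy <- function(seed = 42, n_obs = 8, n_theta = 3) {
  with_seed(seed, {
    G <- matrix(rnorm(n_obs * n_theta), n_obs)
    sig <- runif(n_obs, 0.2, 0.5)
    theta <- rnorm(n_theta)
    list(G = G, sig = sig, theta = theta,
         eta = as.vector(G %*% theta),
         resolve = function(y) {
           obj <- function(th) 0.5 * sum(((y - G %*% th) / sig)^2)
           gr <- function(th)
             -as.vector(crossprod(G, (y - G %*% th) / sig^2))
           stats::nlminb(theta, obj, gr)$par
         },
         closed_form_cov = solve(crossprod(G / sig)))
  })
}
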