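test_that("zero-variance perturbations return the MAP point exactly", {
  des <- build_design(1)
  p <- community_parameters("sp1", 0.5, matrix(-1, 1, 1))
  data <- generate_dataset(p, des, seed = 3)
  fit <- map_estimate(des, data, prior = prior_spec("L2"))
  nlp <- fit$nlp
  resolve <- function(eta_pert) {
    nlp2 <- nlp
    nlp2$exps[[1]]$obs$eta <- eta_pert
    unname(solve_nlp(nlp2, unname(fit$theta))$theta_star)
  }
  draws <- rmap_draws(nlp$exps[[1]]$obs$eta, std = 0, resolve,
                      n_samples = 4, seed = 1)
  for (b in 1:4) expect_identical(draws[b, ], unname(fit$theta))
})

test_that("rMAP sampling is deterministic given the seed and respects bounds", {
  des <- build_design(1)
  p <- community_parameters("sp1", 0.5, matrix(-1, 1, 1))
  data <- generate_dataset(p, des, seed = 3)
  fit <- map_estimate(des, data, prior = prior_spec("L2"))
  s1 <- rmap_sample(fit, n_samples = 12, spec = perturbation_spec(seed = 5))
  s2 <- rmap_sample(fit, n_samples = 12, spec = perturbation_spec(seed = 5))
  expect_identical(s1$samples, s2$samples)
  b <- fit$nlp$bounds
  ok <- stats::complete.cases(s1$samples)
  expect_true(all(t(s1$samples[ok, ]) >= b$lower - 1e-9))
  expect_true(all(t(s1$samples[ok, ]) <= b$upper + 1e-9))
})

test_that("rMAP covariance matches the closed form on a linear toy", {
  toy <- linear_toy()
  draws <- rmap_draws(toy$eta, toy$sig, toy$resolve, 500, seed = 7)
  emp <- stats::cov(draws)
  cf <- toy$closed_form_cov
  expect_lt(norm(emp - cf, "F") / norm(cf, "F"), 0.2)
  expect_lt(max(abs(colMeans(draws) - toy$theta)), 0.2 * max(sqrt(diag(cf))) * 3)
})

test_that("rMAP and reduced-Hessian covariances agree on an observable fit", {
  des <- build_design(1)
  p <- community_parameters("sp1", 0.5, matrix(-1, 1, 1))
  data <- generate_dataset(p, des, seed = 3)
  fit <- map_estimate(des, data, prior = prior_spec("none"))
  ob <- observability_test(fit$nlp, fit$result)
  expect_length(ob$active_bounds, 0L)
  samp <- rmap_sample(fit, n_samples = 400,
                      spec = perturbation_spec(seed = 9))
  emp <- stats::cov(samp$samples[stats::complete.cases(samp$samples), ])
  expect_lt(norm(emp - ob$covariance, "F") / norm(ob$covariance, "F"), 0.3)
})

test_that("posterior summaries: moments, correlations, degenerate columns", {
  X <- with_seed(11, matrix(rnorm(4000), ncol = 4))
  X[, 4] <- X[, 3]
  sm <- summarize_posterior(X)
  expect_equal(sm$correlation[3, 4], 1)
  expect_true(all(abs(sm$correlation) <= 1 + 1e-12))
  expect_equal(diag(sm$correlation), rep(1, 4))
  # fourth >= third^2 + 1 (moment inequality) on samples
  expect_true(all(sm$moment4 >= sm$moment3^2 + 1 - 1e-8))
  Xc <- cbind(X[, 1], 2)
  smc <- summarize_posterior(Xc)
  expect_equal(smc$std[2], 0)
  expect_true(smc$zero_variance[2])
  expect_equal(smc$correlation[1, 2], 0)
  expect_error(summarize_posterior(X[1, , drop = FALSE]), "two valid")
})

test_that("confidence ellipses: chi-square radius, axes, coverage", {
  ce <- confidence_ellipse(diag(2))
  expect_equal(ce$q, stats::qchisq(0.95, 2))
  expect_equal(unname(ce$semi_axes), rep(sqrt(5.991), 2), tolerance = 1e-3)
  ced <- confidence_ellipse(diag(c(4, 1)))
  expect_equal(abs(ced$axes[, 1]), c(1, 0))   # axis-aligned
  C <- matrix(c(2, 0.7, 0.7, 1), 2)
  X <- with_seed(13, matrix(rnorm(2e4), ncol = 2) %*% chol(C))
  d <- rowSums((X %*% solve(C)) * X)
  expect_lt(abs(mean(d <= confidence_ellipse(C)$q) - 0.95), 0.01)
  expect_true(confidence_ellipse(matrix(c(1, 1, 1, 1), 2))$degenerate)
})
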