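test_that("logistic toy: parameters recovered from noiseless data", {
  des <- build_design(1)
  truth <- community_parameters("sp1", 0.5, matrix(-1, 1, 1))
  # noiseless observations with a tiny nominal sigma; negligible prior
  data <- generate_dataset(truth, des, noise_model(1e-4, 1e-3), seed = 1)
  data$abundance <- attr(data, "truth")   # noiseless observations
  fit <- map_estimate(des, data, prior = prior_spec("L2", sd = 1e3),
                      grids = build_grids(des, mono_substeps = 200))
  expect_equal(fit$status, "optimal")
  expect_lt(max(abs(fit$theta - c(0.5, -1))), 1e-3)
})

test_that("solve returns a genuine KKT point with multipliers", {
  f <- fixture_fit3()
  r <- f$fit$result
  expect_equal(r$status, "optimal")
  expect_lt(r$constraint_violation, 1e-10)
  # stationarity on the states is exact by the adjoint construction; on
  # the parameters it is bounded by the optimizer's first-order
  # tolerance, scaled by the objective magnitude
  expect_lt(r$stationarity, 1e-3 * (1 + abs(r$objective)))
  expect_length(r$lambda, f$fit$nlp$n_cons)
  # re-solving from the returned optimum stays there
  r2 <- solve_nlp(f$fit$nlp, warm_start_from(r))
  expect_equal(r2$status, "optimal")
  expect_lt(abs(r2$objective - r$objective), 1e-6 * (1 + abs(r$objective)))
})

test_that("warm starts converge in far fewer iterations than cold starts", {
  f <- fixture_fit3()
  cold <- f$fit$result
  warm <- solve_nlp(f$fit$nlp, warm_start_from(cold))
  expect_lt(warm$iterations, cold$iterations / 2)
  ws <- warm_start_from(cold)
  expect_identical(ws$lambda, cold$lambda)   # multipliers round-trip
  expect_error(warm_start_from(list(status = "error")), "optimal")
})

test_that("default initialization interpolates the data and is deterministic", {
  d <- fixture_small2()
  w1 <- default_initialization(d$nlp, seed = 5)
  w2 <- default_initialization(d$nlp, seed = 5)
  expect_identical(w1, w2)
  ex <- d$nlp$exps[[1]]
  i <- 10
  expect_equal(w1[ex$obs$var[i]], max(ex$obs$eta[i], 1e-6))
  # all-zero data floors the states at the positivity floor
  dz <- d$data; dz$abundance[] <- 0
  nlp0 <- transcribe("glv", d$design, dz, prior = prior_spec("L2"),
                     grids = d$grids)
  w0 <- default_initialization(nlp0)
  expect_true(all(w0[-seq_len(nlp0$n_theta)] >= 1e-6 - 1e-15))
})

test_that("contradictory bounds are rejected before any solve", {
  d <- fixture_small2()
  nlp <- d$nlp
  nlp$lb[1] <- 5; nlp$ub[1] <- 1
  expect_error(solve_nlp(nlp), "contradictory")
})

test_that("multistart returns the best optimal result reproducibly", {
  des <- build_design(1)
  truth <- community_parameters("sp1", 0.5, matrix(-1, 1, 1))
  data <- generate_dataset(truth, des, seed = 6)
  nlp <- transcribe("glv", des, data, prior = prior_spec("L2"),
                    grids = build_grids(des))
  ms1 <- multistart(nlp, 3, seed = 21)
  ms2 <- multistart(nlp, 3, seed = 21)
  expect_equal(ms1$best$objective, ms2$best$objective)
  expect_equal(ms1$objectives, ms2$objectives)
  expect_equal(ms1$best$objective, min(ms1$objectives))
  # a single start equals the default-initialization solve
  one <- multistart(nlp, 1, seed = 3)
  direct <- solve_nlp(nlp)
  expect_equal(one$best$objective, direct$objective, tolerance = 1e-10)
  # all starts of this well-posed scalar problem agree
  expect_lt(diff(range(ms1$objectives)), 1e-4 * (1 + min(ms1$objectives)))
})

test_that("objective at the solution does not exceed the initial objective", {
  d <- fixture_small2()
  red <- glvdirect:::make_reduced(d$nlp, need_grad = FALSE)
  theta0 <- default_initialization(d$nlp)[seq_len(d$nlp$n_theta)]
  res <- solve_nlp(d$nlp)
  expect_lte(res$objective, red$objective(theta0))
})

test_that("recovery error decreases monotonically as noise shrinks", {
  des <- build_design(2)
  params <- draw_parameters(2, seed = 31)
  pm <- class_mean_prior(2)
  # the transcription step size shrinks with the noise so that
  # discretization error stays below the statistical error
  study <- list(list(0.05, 10, 1920), list(0.01, 20, 3840),
                list(0.001, 40, 7680))
  rmse <- vapply(study, function(cs) {
    data <- generate_dataset(params, des, noise_model(scale = cs[[1]]),
                             seed = 77)
    fit <- map_estimate(des, data, prior = pm,
                        grids = build_grids(des, cs[[2]], cs[[3]]),
                        options = solver_options(max_iterations = 2000L))
    sqrt(mean((fit$theta - theta_pack(params))^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})
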