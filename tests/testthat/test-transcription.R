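test_that("transcription bookkeeping: degrees of freedom and bounds", {
  d <- fixture_small2()
  nlp <- d$nlp
  expect_equal(nlp$n_vars - nlp$n_cons, nlp$n_theta)
  expect_equal(nlp$n_theta, 6L)
  # CVaR adds gamma (one degree of freedom) and per-experiment slacks
  nc <- transcribe("glv", d$design, d$data, prior = prior_spec("L2"),
                   cvar = cvar_spec(0.9), grids = d$grids)
  free_rows <- sum(nc$cu > nc$cl)   # one-sided slack rows
  expect_equal(nc$n_vars - (nc$n_cons - free_rows) - free_rows,
               nc$n_theta + 1L)
  # parameter bounds are the biological box
  b <- nlp$bounds
  expect_equal(unname(b$lower[c("mu[sp1]", "alpha[sp1,sp1]",
                                "alpha[sp1,sp2]")]),
               c(0.09, -10, -10))
  expect_equal(unname(b$upper[c("mu[sp1]", "alpha[sp1,sp1]",
                                "alpha[sp1,sp2]")]),
               c(2.1, 0, 10))
  expect_error(default_parameter_bounds("a", mu_range = c(2, 1)),
               "lower")
})

test_that("constraints vanish at states produced by forward propagation", {
  d <- fixture_small2()
  nlp <- d$nlp
  theta <- default_initialization(nlp)[seq_len(nlp$n_theta)]
  pt <- glvdirect:::make_reduced(nlp)$evalpt(theta)
  w <- glvdirect:::reconstruct_w(nlp, theta, pt)
  expect_lt(max(abs(evaluate_constraints(nlp, w))), 1e-12)
})

test_that("objective values: vanishing at prior mean/perfect fit, 0.5 per sigma", {
  d <- fixture_small2()
  # build a dataset equal to the propagated outputs so eta == eta_bar
  nlp <- d$nlp
  theta <- default_initialization(nlp)[seq_len(nlp$n_theta)]
  pt <- glvdirect:::make_reduced(nlp)$evalpt(theta)
  w <- glvdirect:::reconstruct_w(nlp, theta, pt)
  nlp0 <- nlp
  nlp0$prior <- glvdirect:::expand_prior(
    prior_spec("L2", mean = theta, sd = 1 / 50), nlp$n_theta)
  for (k in seq_along(nlp0$exps))
    nlp0$exps[[k]]$obs$eta <- w[nlp0$exps[[k]]$obs$var]
  expect_equal(evaluate_objective(nlp0, w), 0)
  # a single residual of size sigma contributes exactly 1/2
  nlp1 <- nlp0
  nlp1$exps[[1]]$obs$eta[1] <- nlp1$exps[[1]]$obs$eta[1] +
    nlp1$exps[[1]]$obs$sigma[1]
  expect_equal(evaluate_objective(nlp1, w), 0.5)
})

test_that("analytic derivatives match finite differences (both model forms)", {
  d <- fixture_small2()
  for (form in c("glv", "saturable")) {
    params <- draw_parameters(2, seed = 8, model_form = form)
    data <- generate_dataset(params, d$design, seed = 4,
                             model_form = form)
    nlp <- transcribe(form, d$design, data, prior = prior_spec("L2"),
                      grids = d$grids)
    theta <- default_initialization(nlp)[seq_len(nlp$n_theta)]
    theta <- theta + abs(with_seed(1, rnorm(nlp$n_theta, sd = 0.02)))
    pt <- glvdirect:::make_reduced(nlp)$evalpt(theta)
    w <- glvdirect:::reconstruct_w(nlp, theta, pt) +
      abs(with_seed(2, rnorm(nlp$n_vars, sd = 0.01)))
    lam <- with_seed(3, rnorm(nlp$n_cons))
    der <- evaluate_derivatives(nlp, w, lam)
    fg <- fd_gradient(function(v) evaluate_objective(nlp, v), w)
    expect_lt(max(abs(fg - der$gradient)) / max(abs(der$gradient)), 1e-6)
    fj <- fd_jacobian(function(v) evaluate_constraints(nlp, v), w)
    expect_lt(max(abs(fj - as.matrix(der$jacobian))) /
                max(abs(der$jacobian)), 1e-6)
    lagr <- function(v) evaluate_objective(nlp, v) +
      sum(lam * evaluate_constraints(nlp, v))
    idx <- with_seed(4, sample(nlp$n_vars, 25))
    H <- as.matrix(der$hessian)
    for (a in idx[1:5]) {
      fh <- fd_gradient(function(v) {
        e <- numeric(nlp$n_vars); e[a] <- 1e-5
        (lagr(v + e) - lagr(v - e)) / 2e-5
      }, w, h = 1e-5)
      expect_lt(max(abs(fh - H[a, ])) / max(1, max(abs(H))), 1e-4)
    }
  }
})

test_that("CVaR and L1 transcriptions evaluate consistently", {
  d <- fixture_small2()
  nc <- transcribe("glv", d$design, d$data, prior = prior_spec("L2"),
                   cvar = cvar_spec(0.9), grids = d$grids)
  theta <- default_initialization(nc)[seq_len(nc$n_theta)]
  pt <- glvdirect:::make_reduced(nc, need_grad = FALSE)$evalpt(theta)
  w <- glvdirect:::reconstruct_w(nc, theta, pt)
  # slack rows are feasible and the objective equals the minimized CVaR
  cons <- evaluate_constraints(nc, w)
  expect_true(all(cons[nc$cvar_con] >= -1e-10))
  expect_equal(evaluate_objective(nc, w),
               0.5 * sum(((theta - nc$prior$mean) / nc$prior$sd)^2) +
                 cvar_objective_value(pt$e, 0.9)$minimized$objective,
               tolerance = 1e-10)
  # gradient of the CVaR transcription matches finite differences
  der <- evaluate_derivatives(nc, w)
  fg <- fd_gradient(function(v) evaluate_objective(nc, v), w)
  expect_lt(max(abs(fg - der$gradient)) / max(abs(der$gradient)), 1e-6)
  # L1 split: complementarity and reconstruction at any represented point
  nl <- transcribe("glv", d$design, d$data, prior = prior_spec("L1"),
                   grids = d$grids)
  wl <- default_initialization(nl)
  tp <- wl[nl$l1_pos]; tn <- wl[nl$l1_neg]
  expect_equal(tp * tn, numeric(nl$n_theta))
  expect_equal(tp + tn,
               abs(wl[seq_len(nl$n_theta)] - nl$prior$mean))
  expect_lt(max(abs(evaluate_constraints(nl, wl)[nl$l1_con])), 1e-12)
})

test_that("CVaR objective: brute-force oracle, limits, monotonicity", {
  e <- c(4.2, 1.1, 9.5, 0.3, 7.7, 2.2, 5.5, 3.3, 8.8, 6.6)
  for (beta in c(0, 0.25, 0.5, 0.9, 0.99)) {
    expect_equal(cvar_objective_value(e, beta)$minimized$objective,
                 cvar_brute(e, beta), tolerance = 1e-3)
  }
  expect_equal(cvar_objective_value(e, 0)$minimized$objective, sum(e))
  expect_equal(cvar_objective_value(e, 0.999)$minimized$cvar, max(e),
               tolerance = 1e-9)
  expect_equal(cvar_objective_value(1:10, 0.9)$minimized$cvar, 10)
  expect_equal(cvar_objective_value(rep(3.7, 8), 0.6)$minimized$cvar, 3.7)
  cv <- vapply(seq(0, 0.95, 0.05), function(b)
    cvar_objective_value(e, b)$minimized$cvar, numeric(1))
  expect_true(all(diff(cv) >= -1e-12))
})

test_that("discretization criterion arithmetic", {
  fake <- function(theta_pair) {
    i <- 0
    function(grids) { i <<- i + 1; theta_pair[[i]] }
  }
  chk <- check_discretization(fake(list(c(a = 1.0), c(a = 1.005))),
                              grids = list())
  expect_true(chk$verdict)           # relative 0.005 < 0.01
  chk2 <- check_discretization(fake(list(c(a = 0.5), c(a = 0.53))),
                               grids = list())
  expect_false(chk2$verdict)         # abs 0.03, rel 0.06
  chk3 <- check_discretization(fake(list(c(a = 2), c(a = 2))),
                               grids = list())
  expect_true(chk3$verdict)
})
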