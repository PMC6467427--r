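test_that("compiled propagation matches the pure-R reference exactly", {
  des <- build_design(2)
  ex <- des$experiments[[3]]
  g <- build_grid(ex, pairwise_n_intervals = 240)
  for (form in c("glv", "saturable")) {
    pp <- draw_parameters(2, seed = 7, model_form = form)
    lmap <- glvdirect:::local_theta_map(1:2, 2, form)
    lp <- glvdirect:::local_lp(theta_pack(pp)[lmap], 2, form)
    a <- glvdirect:::propagate_grid(lp, g, ex$initial_abundances, form,
                                    sens = TRUE)
    b <- glvdirect:::propagate_grid_r(lp, g, ex$initial_abundances, form,
                                      sens = TRUE)
    expect_true(a$ok && b$ok)
    expect_equal(a$states, b$states, tolerance = 1e-12)
    expect_equal(a$sens, b$sens, tolerance = 1e-10)
  }
})

test_that("one implicit Euler step solves its defining nonlinear equation", {
  # xdot = -x^2 from x0 = 1, h = 1: root of z^2 + z - 1
  z <- glvdirect:::implicit_step_scalar_glv(1, 1, 0, -1)
  expect_equal(z, (-1 + sqrt(5)) / 2, tolerance = 1e-12)
  # and the step with no nonnegative solution is rejected
  expect_null(glvdirect:::implicit_step_scalar_glv(0.01, 8, 0.25, 0))
})

test_that("propagation sensitivities match finite differences", {
  des <- build_design(2)
  ex <- des$experiments[[3]]
  g <- build_grid(ex, pairwise_n_intervals = 60)
  pp <- draw_parameters(2, seed = 3)
  lmap <- glvdirect:::local_theta_map(1:2, 2, "glv")
  tl <- theta_pack(pp)[lmap]
  pg <- glvdirect:::propagate_grid(glvdirect:::local_lp(tl, 2, "glv"),
                                   g, ex$initial_abundances, "glv",
                                   sens = TRUE)
  final <- function(t) {
    r <- glvdirect:::propagate_grid(glvdirect:::local_lp(t, 2, "glv"),
                                    g, ex$initial_abundances, "glv")
    r$states[nrow(r$states), ]
  }
  J <- length(g$times)
  fd <- fd_jacobian(final, tl)
  expect_equal(matrix(pg$sens[J, , ], 2), fd, tolerance = 1e-5)
})

test_that("implicit Euler converges to the reference at first order", {
  des <- build_design(2)
  ex <- des$experiments[[3]]
  pp <- draw_parameters(2, seed = 7)
  tr <- simulate_experiment(pp, ex)
  truth <- trajectory_at(tr, ex$sampling_times_h)
  lmap <- glvdirect:::local_theta_map(1:2, 2, "glv")
  lp <- glvdirect:::local_lp(theta_pack(pp)[lmap], 2, "glv")
  errs <- vapply(c(120, 240, 480, 960), function(n) {
    g <- build_grid(ex, pairwise_n_intervals = n)
    pg <- glvdirect:::propagate_grid(lp, g, ex$initial_abundances, "glv")
    max(abs(pg$states[g$sample_node, ] - truth))
  }, numeric(1))
  order <- -diff(log2(errs))
  expect_true(all(order > 0.8 & order < 1.2))
})
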