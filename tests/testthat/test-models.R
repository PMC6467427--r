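test_that("gLV right-hand side matches hand arithmetic and fixed points", {
  p1 <- community_parameters("a", 0.3, matrix(-1, 1, 1))
  # equilibrium x* = -mu/alpha
  expect_equal(glv_rhs(0.3, p1), 0)
  # extinction is absorbing
  expect_equal(glv_rhs(0, p1), 0)
  p2 <- community_parameters(c("a", "b"), c(0.3, 0.3),
                             matrix(c(-1, -0.2, 0.1, -1), 2, 2))
  expect_equal(glv_rhs(c(0.5, 0.2), p2), c(-0.09, 0), tolerance = 1e-12)
  expect_error(glv_rhs(c(1, 1), p2, members = c("a", "zz")),
               "unknown species")
})

test_that("saturable rhs halves interactions at K and loses them as K grows", {
  K <- matrix(1, 2, 2)
  ps <- community_parameters(c("a", "b"), c(0.3, 0.3),
                             matrix(c(-1, 0, 0, -1), 2, 2), K)
  # x' = K: interaction contributes alpha/2 per unit recipient abundance
  r <- saturable_rhs(c(1, 1), ps)
  expect_equal(r, (0.3 - 0.5) * c(1, 1))
  # worked value: (0.3 - 0.5/1.5) * 0.5
  expect_equal(saturable_rhs(c(0.5, 0.5), ps)[1], (0.3 - 0.5 / 1.5) * 0.5,
               tolerance = 1e-12)
  # K -> large: pure growth
  ps2 <- community_parameters(c("a", "b"), c(0.3, 0.3),
                              matrix(c(-1, 0, 0, -1), 2, 2),
                              matrix(1e9, 2, 2))
  expect_equal(saturable_rhs(c(0.5, 0.5), ps2), 0.3 * c(0.5, 0.5),
               tolerance = 1e-6)
  expect_error(community_parameters("a", 1, matrix(-1, 1, 1),
                                    matrix(-2, 1, 1)),
               "strictly positive")
})

test_that("reference simulator matches the logistic closed form", {
  p <- community_parameters("a", 0.5, matrix(-1, 1, 1))
  ex <- experiment("m", "a", 24, seq(0.5, 24, 0.5), 0.01)
  tr <- simulate_experiment(p, ex)
  logistic <- function(t) 0.5 * 0.01 * exp(0.5 * t) /
    (0.5 + 0.01 * (exp(0.5 * t) - 1))
  at <- trajectory_at(tr, c(2, 10, 24))
  expect_equal(as.vector(at), logistic(c(2, 10, 24)), tolerance = 1e-7)
  expect_equal(at[2], 0.3759, tolerance = 1e-4)
})

test_that("dilution events are instantaneous 1/20 jumps with both values stored", {
  p <- community_parameters("a", 0.5, matrix(-1, 1, 1))
  ex <- experiment("d", "a", 48, seq(12, 48, 12), 0.01,
                   dilution_times_h = 24, dilution_factor = 1 / 20)
  tr <- simulate_experiment(p, ex)
  i <- which(tr$times == 24)
  expect_length(i, 2L)
  expect_equal(tr$states[i[2]], tr$states[i[1]] / 20)
  expect_true(tr$post_dilution[i[2]] && !tr$post_dilution[i[1]])
  # sampling at a dilution instant returns the pre-dilution value
  expect_equal(trajectory_at(tr, 24)[1], tr$states[i[1]])
})

test_that("zero initial state stays identically zero and positivity holds", {
  p <- draw_parameters(2, seed = 5)
  ex <- experiment("p", c("sp1", "sp2"), 96, seq(12, 96, 12), 0,
                   dilution_times_h = c(24, 48, 72),
                   dilution_factor = 1 / 20)
  tr <- simulate_experiment(p, ex)
  expect_true(all(tr$states == 0))
  ex2 <- experiment("p2", c("sp1", "sp2"), 96, seq(12, 96, 12), 0.01,
                    dilution_times_h = c(24, 48, 72),
                    dilution_factor = 1 / 20)
  tr2 <- simulate_experiment(p, ex2)
  expect_true(all(tr2$states >= -1e-9))
})

test_that("parameter CSV round-trips", {
  p <- draw_parameters(3, seed = 2, model_form = "saturable")
  stem <- file.path(tempdir(), "pars")
  write_parameters_csv(p, stem)
  q <- read_parameters_csv(stem)
  expect_equal(theta_pack(q), theta_pack(p), tolerance = 1e-12)
})
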