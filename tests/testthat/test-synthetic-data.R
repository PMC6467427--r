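test_that("full designs reproduce the published problem-size identities", {
  # exact counts for the scalability family, all four sizes
  expected <- data.frame(
    S = c(12, 24, 36, 48),
    params = c(156, 600, 1332, 2352),
    odes = c(144, 576, 1296, 2304),
    exps = c(78, 300, 666, 1176),
    points = c(1632, 5568, 11808, 20352))
  for (i in seq_len(nrow(expected))) {
    sm <- summarize_design(build_design(expected$S[i]))
    expect_equal(sm$n_parameters, expected$params[i])
    expect_equal(sm$n_differential_equations, expected$odes[i])
    expect_equal(sm$n_experiments, expected$exps[i])
    expect_equal(sm$n_data_points, expected$points[i])
    # generic identities
    S <- expected$S[i]
    expect_equal(sm$n_experiments, S * (S + 1) / 2)
    expect_equal(sm$n_differential_equations, S^2)
  }
  s1 <- summarize_design(build_design(1))
  expect_equal(s1$n_parameters, 2)
  expect_equal(s1$n_experiments, 1)
  expect_equal(s1$n_data_points, 48)
  expect_equal(summarize_design(build_design(24),
                                model_form = "saturable")$n_parameters,
               2 * 24^2 + 24)
})

test_that("parameter draws follow the stated distributions and are seeded", {
  a <- draw_parameters(12, seed = 4)
  b <- draw_parameters(12, seed = 4)
  expect_identical(theta_pack(a), theta_pack(b))
  expect_length(theta_pack(a), 156)
  expect_true(all(is.finite(theta_pack(a))))
  big <- draw_parameters(200, seed = 11)
  expect_lt(abs(mean(diag(big$interactions)) + 1), 3 * 0.1 / sqrt(200))
  expect_lt(abs(mean(big$growth_rates) - 0.3), 3 * 0.1 / sqrt(200))
  off <- big$interactions[row(big$interactions) != col(big$interactions)]
  expect_lt(abs(mean(off)), 3 * 0.1 / sqrt(length(off)))
})

test_that("noise rule and record counts of generated data sets", {
  nm <- noise_model()
  expect_equal(noise_std(nm, 1.0), 0.05)
  expect_equal(noise_std(nm, 0.02), 0.005)   # floor active
  d <- fixture_small2()
  expect_equal(nrow(d$data), 2 * 48 + 2 * 8)
  expect_true(all(d$data$std > 0))
  expect_true(all(d$data$abundance >= 0))
  # generation is deterministic given the seed
  again <- generate_dataset(d$params, d$design, seed = 3)
  expect_identical(d$data$abundance, again$abundance)
})

test_that("noise calibration: standardized deviations have unit variance", {
  d <- fixture_small2()
  z <- (d$data$abundance - attr(d$data, "truth")) / d$data$std
  # clipping at zero affects a negligible share here
  expect_lt(abs(mean(z^2) - 1), 4 * sqrt(2 / length(z)))
})

test_that("replicated augmentation multiplies experiments and records", {
  d <- fixture_small2()
  aug <- augment_with_replicates(d$data, 2, seed = 9)
  expect_equal(nrow(aug), 3 * nrow(d$data))
  expect_equal(length(unique(aug$experiment_id)),
               3 * length(unique(d$data$experiment_id)))
  expect_identical(augment_with_replicates(d$data, 0, seed = 1), d$data)
  rd <- replicate_design(d$design, 2)
  expect_equal(summarize_design(rd)$n_experiments, 9)
  # perturbed copies differ from the base but share its std
  expect_false(all(aug$abundance[nrow(d$data) + seq_len(nrow(d$data))] ==
                     d$data$abundance))
})

test_that("measurement and design serialization round-trip", {
  d <- fixture_small2()
  f <- file.path(tempdir(), "meas.csv")
  write_measurements_csv(d$data, f)
  back <- read_measurements_csv(f)
  expect_equal(back$abundance, d$data$abundance, tolerance = 1e-12)
  dj <- file.path(tempdir(), "design.json")
  write_design(d$design, dj)
  back_d <- read_design(dj)
  expect_equal(summarize_design(back_d), summarize_design(d$design))
  expect_equal(back_d$experiments[[3]]$dilution_times_h,
               d$design$experiments[[3]]$dilution_times_h)
})
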