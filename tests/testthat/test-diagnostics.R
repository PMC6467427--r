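make_error_fixture <- function() {
  data <- data.frame(
    experiment_id = rep(c("e1", "e2"), each = 3),
    species = "a",
    time_h = rep(c(1, 2, 3), 2),
    abundance = c(1, 1, 1, 2, 2, 2),
    std = rep(0.5, 6))
  pred <- data
  names(pred)[names(pred) == "abundance"] <- "predicted"
  pred$predicted <- c(1, 1.5, 1, 2, 2, 3)   # residuals 0, sigma, 0, 0, 0, 2*sigma
  pred$std <- NULL
  list(data = data, pred = pred)
}

test_that("fitting errors: per-point, per-series and overall additivity", {
  fx <- make_error_fixture()
  tab <- fitting_errors(fx$data, fx$pred)
  expect_equal(tab$points$value, c(0, 0.5, 0, 0, 0, 2))
  expect_equal(tab$series$value, c(0.5, 2))
  expect_equal(tab$overall, sum(tab$points$value))
  # perfect predictions give all zeros
  perf <- fx$pred; perf$predicted <- fx$data$abundance
  expect_equal(fitting_errors(fx$data, perf)$overall, 0)
  # missing prediction is an error naming the record
  expect_error(fitting_errors(fx$data, fx$pred[-2, ]), "no prediction")
})

test_that("top-k ranking with lexicographic tie-breaks", {
  fx <- make_error_fixture()
  tab <- fitting_errors(fx$data, fx$pred)
  top2 <- top_k_errors(tab, 2)
  expect_equal(top2$value, c(2, 0.5))
  expect_false(attr(top2, "short_supply"))
  all6 <- top_k_errors(tab, 6)
  expect_equal(all6$value, sort(tab$points$value, decreasing = TRUE))
  # ties resolve by (experiment, species, time)
  tied <- all6[all6$value == 0, ]
  expect_equal(order(tied$experiment_id, tied$time_h), seq_len(nrow(tied)))
  over <- top_k_errors(tab, 10)
  expect_equal(nrow(over), 6)
  expect_true(attr(over, "short_supply"))
  expect_equal(nrow(top_k_errors(tab, 1, granularity = "series")), 1)
})

test_that("tail means: counting definition and monotonicity in the fraction", {
  tm <- tail_mean(1:10, 0.1)
  expect_equal(tm$tail_mean, 10)
  expect_equal(tm$overall_mean, 5.5)
  expect_equal(tail_mean(1:10, 1)$tail_mean, 5.5)
  expect_equal(tail_mean(rep(3, 7), 0.4)$tail_mean, 3)
  fr <- seq(0.05, 1, 0.05)
  tms <- vapply(fr, function(f) tail_mean(1:37, f)$tail_mean, numeric(1))
  expect_true(all(diff(tms) <= 1e-12))
  expect_error(tail_mean(numeric(0)), "non-empty")
})

test_that("fitted measurements line up with the data records", {
  d <- fixture_small2()
  fit <- map_estimate(d$design, d$data, prior = class_mean_prior(2),
                      grids = d$grids)
  fm <- fitted_measurements(fit)
  expect_equal(nrow(fm), nrow(d$data))
  tab <- fitting_errors(d$data, fit)
  expect_true(all(tab$points$value >= 0))
  hist <- error_histogram(tab, breaks = 10)
  expect_equal(sum(hist$count), nrow(d$data))
})
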