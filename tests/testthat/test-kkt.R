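test_that("LDL^T inertia agrees with the eigendecomposition oracle", {
  expect_equal(unname(inertia(diag(5))), c(5L, 0L, 0L))
  expect_equal(unname(inertia(diag(c(2, -5, 0)))), c(1L, 1L, 1L))
  expect_equal(unname(inertia(matrix(0, 3, 3))), c(0L, 0L, 3L))
  with_seed(12, {
    for (i in 1:20) {
      A <- random_symmetric(20)
      expect_equal(unname(inertia(A)), eigen_inertia(A))
    }
  })
  expect_error(inertia(matrix(1:6, 2, 3)), "square")
  expect_error(inertia(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("augmented KKT matrix structure and residuals at a solution", {
  d <- fixture_small2()
  res <- solve_nlp(d$nlp)
  kkt0 <- assemble_kkt(d$nlp, res, kappa_w = 0)
  expect_lt(kkt0$residuals$primal, 1e-10)
  expect_lt(kkt0$residuals$stationarity, 1e-8)
  expect_equal(dim(kkt0$M), rep(d$nlp$n_vars + d$nlp$n_cons, 2))
  # kappa_w shifts exactly the first n diagonal entries by identity
  kkt1 <- assemble_kkt(d$nlp, res, kappa_w = 1)
  D <- kkt1$M - kkt0$M
  expect_equal(as.vector(Matrix::diag(D)),
               c(rep(1, d$nlp$n_vars), rep(0, d$nlp$n_cons)))
  expect_equal(Matrix::nnzero(D), d$nlp$n_vars)
  # missing multipliers are rejected
  res2 <- res; res2$lambda <- NULL
  expect_error(assemble_kkt(d$nlp, res2), "multipliers")
})

test_that("BBD split is an exact symmetric permutation of the KKT matrix", {
  d <- fixture_small2()
  res <- solve_nlp(d$nlp)
  kkt <- assemble_kkt(d$nlp, res)
  bbd <- split_bbd(kkt)
  M <- as.matrix(kkt$M)
  expect_equal(max(abs(M[bbd$perm, bbd$perm] - bbd_matrix(bbd))), 0)
})

test_that("Schur solve equals a direct solve of the full system", {
  d <- fixture_small2()
  res <- solve_nlp(d$nlp)
  kkt <- assemble_kkt(d$nlp, res)
  bbd <- split_bbd(kkt)
  rhs <- with_seed(3, rnorm(kkt$n + kkt$m))
  sol <- schur_solve(bbd, rhs[bbd$perm])
  direct <- as.vector(Matrix::solve(
    methods::as(kkt$M, "generalMatrix"), rhs))[bbd$perm]
  expect_lt(max(abs(sol$x - direct)) / max(abs(direct)), 1e-8)
  # zero right-hand side gives the zero solution
  expect_equal(schur_solve(bbd, numeric(kkt$n + kkt$m))$x,
               numeric(kkt$n + kkt$m))
})

test_that("Haynsworth additivity on random block-bordered systems", {
  with_seed(7, {
    for (i in 1:25) {
      p <- sample(2:5, 1)
      nb <- sample(1:3, 1)
      sizes <- replicate(nb, {
        n_k <- sample(4:9, 1); c(n_k, sample(2:n_k, 1))
      }, simplify = FALSE)
      bbd <- random_bbd(p, sizes)
      rep <- bbd_inertia(bbd)
      expect_equal(c(rep$n_plus, rep$n_minus, rep$n_zero),
                   eigen_inertia(bbd_matrix(bbd)))
    }
  })
})

test_that("regularization monotonicity: kappa_w pushes inertia positive", {
  d <- fixture_small2()
  res <- solve_nlp(d$nlp)
  prev_plus <- -1L; prev_rest <- .Machine$integer.max
  for (k in c(0, 0.1, 1, 10)) {
    kkt <- assemble_kkt(d$nlp, res, kappa_w = k)
    ine <- inertia(kkt$M)
    expect_gte(ine[["n_plus"]], prev_plus)
    expect_lte(ine[["n_minus"]] + ine[["n_zero"]], prev_rest)
    prev_plus <- ine[["n_plus"]]
    prev_rest <- ine[["n_minus"]] + ine[["n_zero"]]
  }
})

test_that("observability: informative data observable, duplicated column not", {
  des <- build_design(1)
  p <- community_parameters("sp1", 0.5, matrix(-1, 1, 1))
  data <- generate_dataset(p, des, seed = 3)
  fit <- map_estimate(des, data, prior = prior_spec("none"))
  ob <- observability_test(fit$nlp, fit$result)
  expect_equal(ob$report$verdict, "observable")
  expect_true(all(diag(ob$covariance) > 0))
  # linear-Gaussian block: reduced Hessian inverse is (G' S^-1 G)^-1
  with_seed(9, {
    G <- matrix(rnorm(12), 6, 2)
    sig <- runif(6, 0.5, 2)
    Kk <- rbind(cbind(diag(1 / sig^2), diag(6)),
                cbind(diag(6), matrix(0, 6, 6)))
    bbd <- bbd_system(matrix(0, 2, 2),
                      list(list(K = Kk,
                                B = cbind(matrix(0, 2, 6), t(-G)),
                                n_k = 6, m_k = 6)))
    rep <- bbd_inertia(bbd)
    expect_equal(rep$verdict, "observable")
    expect_equal(solve(rep$S), solve(crossprod(G / sig)),
                 tolerance = 1e-8)
    # duplicate a parameter column: theta1 and theta2 enter as a sum
    G2 <- cbind(G[, 1], G[, 1])
    bbd2 <- bbd_system(matrix(0, 2, 2),
                       list(list(K = Kk,
                                 B = cbind(matrix(0, 2, 6), t(-G2)),
                                 n_k = 6, m_k = 6)))
    rep2 <- bbd_inertia(bbd2)
    expect_equal(rep2$verdict, "not_observable")
    expect_gte(rep2$schur_inertia[["n_zero"]], 1L)
    # an L2 prior adds its precision to the Schur complement and
    # restores observability
    bbd3 <- bbd_system(diag(2500, 2),
                       list(list(K = Kk,
                                 B = cbind(matrix(0, 2, 6), t(-G2)),
                                 n_k = 6, m_k = 6)))
    expect_equal(bbd_inertia(bbd3)$verdict, "observable")
  })
})

test_that("a species that is never measured makes the problem unobservable", {
  des1 <- build_design(1)
  p <- community_parameters("sp1", 0.5, matrix(-1, 1, 1))
  data <- generate_dataset(p, des1, seed = 3)
  # same data, but the community nominally contains an absent species
  des2 <- structure(list(species_labels = c("sp1", "sp2"),
                         experiments = des1$experiments),
                    class = "experiment_design")
  nlp <- transcribe("glv", des2, data, prior = prior_spec("none"))
  res <- solve_nlp(nlp)
  ob <- observability_test(nlp, res)
  expect_equal(ob$report$verdict, "not_observable")
  expect_gte(ob$report$schur_inertia[["n_zero"]], 4L)
  # reinstating the L2 prior makes the posterior unique
  nlp2 <- transcribe("glv", des2, data, prior = prior_spec("L2"))
  res2 <- solve_nlp(nlp2)
  rep2 <- bbd_inertia(split_bbd(assemble_kkt(nlp2, res2)))
  expect_equal(rep2$verdict, "observable")
})

test_that("coordinate export writes the lower triangle", {
  f <- file.path(tempdir(), "coord.csv")
  write_coordinate(matrix(c(1, 2, 2, 3), 2), f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$i >= tab$j))
})
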