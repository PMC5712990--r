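test_that("scenario counts follow (2^M - 1) * M and the canonical order", {
  for (M in 1:5) {
    expect_length(enumerate_scenarios(M), (2^M - 1) * M)
  }
  sc3 <- enumerate_scenarios(3)
  # first effect's seven cause subsets: singletons, pairs, full set
  first7 <- lapply(sc3[1:7], `[[`, "causes")
  expect_equal(first7, list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L),
                            c(1L, 2L, 3L)))
  expect_equal(vapply(sc3, `[[`, integer(1), "effect"), rep(1:3, each = 7))
  expect_error(enumerate_scenarios(0), "integer")
})

test_that("pw and c-pw reductions keep M^2 scenarios of the right shape", {
  sc3 <- enumerate_scenarios(3)
  pw <- reduce_scenarios(sc3, "pw", 3)
  cpw <- reduce_scenarios(sc3, "c-pw", 3)
  expect_length(pw, 9)
  expect_length(cpw, 9)
  expect_identical(reduce_scenarios(sc3, "complete", 3), sc3)
  # pw for effect 2: {2}, {1,2}, {2,3}
  pw2 <- Filter(function(s) s$effect == 2L, pw)
  expect_equal(lapply(pw2, `[[`, "causes"), list(2L, c(1L, 2L), c(2L, 3L)))
  # c-pw for effect 2: leave-one-out sets {2,3}, {1,2} and the full set
  cpw2 <- Filter(function(s) s$effect == 2L, cpw)
  expect_equal(lapply(cpw2, `[[`, "causes"),
               list(c(1L, 2L), c(2L, 3L), c(1L, 2L, 3L)))
  # the two reductions coincide for M = 2
  sc2 <- enumerate_scenarios(2)
  expect_identical(reduce_scenarios(sc2, "pw", 2),
                   reduce_scenarios(sc2, "c-pw", 2))
  expect_length(reduce_scenarios(sc2, "pw", 2), 4)
  expect_error(reduce_scenarios(sc3, "bogus", 3))
})

test_that("lagged problems assemble the p-step history per cause", {
  set.seed(21)
  X <- matrix(rnorm(50 * 3), 50, 3)
  full <- list(causes = 1:3, effect = 3L)
  pr <- build_lagged_problem(X, full, p = 10)
  expect_equal(dim(pr$design), c(40, 30))
  expect_length(pr$target, 40)
  # the row for 0-based time point t = 30 (row 21): x0(20..29), x1(...), x2(...)
  expect_equal(pr$design[21, ], c(X[21:30, 1], X[21:30, 2], X[21:30, 3]))
  expect_equal(pr$target[21], X[31, 3])
  # single admissible time point when N = p + 1
  one <- build_lagged_problem(X[1:11, ], full, p = 10)
  expect_equal(dim(one$design), c(1, 30))
  # degenerate constant channel
  Xz <- X; Xz[, 2] <- 0
  przz <- build_lagged_problem(Xz, list(causes = 2L, effect = 2L), p = 10)
  expect_true(all(przz$design == 0) && all(przz$target == 0))
  expect_error(build_lagged_problem(X[1:10, ], full, p = 10), "rows")
})

test_that("no value at time >= t leaks into the row for t", {
  set.seed(22)
  X <- matrix(rnorm(60 * 2), 60, 2)
  sc <- list(causes = 1:2, effect = 1L)
  pr1 <- build_lagged_problem(X, sc, p = 5)
  X2 <- X
  X2[41:60, ] <- 999
  pr2 <- build_lagged_problem(X2, sc, p = 5)
  # rows for t < 40 (0-based) are untouched by the future rewrite
  expect_identical(pr1$design[1:35, ], pr2$design[1:35, ])
  expect_identical(pr1$target[1:35], pr2$target[1:35])
})

test_that("OLS scoring matches a brute-force normal-equations oracle", {
  # hand-computable 4-row problem
  design <- cbind(c(0, 1, 2, 3), c(1, 0, 1, 0))
  target <- c(1, 2, 4, 5)
  fit <- fit_and_score(list(design = design, target = target))
  oracle <- ols_normal_eq_oracle(design, target)
  expect_equal(fit$coefficients, oracle$coefficients, tolerance = 1e-8)
  expect_equal(fit$mse, oracle$mse, tolerance = 1e-8)
  # random instances
  set.seed(23)
  for (rep in 1:10) {
    d <- matrix(rnorm(40 * 5), 40, 5)
    y <- rnorm(40)
    f <- fit_and_score(list(design = d, target = y))
    o <- ols_normal_eq_oracle(d, y)
    expect_equal(f$coefficients, o$coefficients, tolerance = 1e-8)
    expect_equal(f$mse, o$mse, tolerance = 1e-8)
    expect_identical(f$rv, f$mse)
  }
})

test_that("OLS handles exact fits, pure noise and degenerate targets", {
  set.seed(24)
  d <- matrix(rnorm(60 * 3), 60, 3)
  y_exact <- drop(d %*% c(1, -2, 0.5)) + 3
  f <- fit_and_score(list(design = d, target = y_exact))
  expect_lt(f$mse, 1e-20)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  # independent noise target: r2 near 0 (order regressors/rows)
  y_noise <- rnorm(2000)
  f2 <- fit_and_score(list(design = matrix(rnorm(2000 * 3), 2000, 3),
                           target = y_noise))
  expect_lt(abs(f2$r2), 3 * 3 / 2000 + 0.01)
  # zero-variance target: r2 = 0 by convention, flagged
  f3 <- fit_and_score(list(design = d, target = rep(2, 60)))
  expect_identical(f3$r2, 0)
  expect_true(f3$zero_variance)
  # rank deficiency: duplicated column, minimum-norm solution
  dd <- cbind(d[, 1], d[, 1], d[, 2])
  f4 <- fit_and_score(list(design = dd, target = y_exact))
  expect_lt(f4$rank, 4)
  expect_equal(f4$coefficients[2], f4$coefficients[3], tolerance = 1e-8)
  expect_true(is.finite(f4$mse))
})
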