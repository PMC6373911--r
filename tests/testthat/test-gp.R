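# Gaussian-process emulator: kernel identities, posterior equations
# against a dense-matrix oracle, interpolation/prior-reversion limits,
# sampling, hyperparameter recovery and leave-one-out equivalence.

test_that("squared-exponential kernel obeys its closed forms", {
  expect_equal(sqexp_kernel(c(1, 2), c(1, 2), sigma = 1.7, phi = 1),
               1.7^2, tolerance = 1e-14)
  expect_equal(sqexp_kernel(0, 1, sigma = 1, phi = 1), exp(-0.5),
               tolerance = 1e-14)
  expect_lt(sqexp_kernel(0, 25, sigma = 1, phi = 1), exp(-200))
  expect_equal(sqexp_kernel(c(0, 0), c(1, 2), 2, c(1, 2)),
               sqexp_kernel(c(1, 2), c(0, 0), 2, c(1, 2)),
               tolerance = 1e-15)
  expect_error(sqexp_kernel(c(1, 2), 1, 1, 1), "dimension mismatch")
  expect_error(sqexp_kernel(1, 2, -1, 1), "must be > 0")
})

test_that("kernel matrices are symmetric positive semi-definite", {
  set.seed(8)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 3), 30, 3)
    sigma <- runif(1, 0.5, 3); phi <- runif(3, 0.3, 3)
    K <- .sqexp_cov(X, X, sigma, phi)
    expect_equal(K, t(K), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sigma^2)
  }
})

test_that("posterior prediction matches the dense-matrix oracle", {
  ## fixed 3-point, 1-d dataset
  gp1 <- gp_emulator(matrix(c(0, 1, 2.5)), c(0.3, 1.1, 0.4),
                     hyper = list(sigma = 1, phi = 0.8),
                     standardize = FALSE, nugget_rel = 1e-10)
  Z1 <- matrix(seq(-0.5, 3, length.out = 11))
  got <- predict(gp1, Z1)
  ora <- oracle_gp_predict(gp1, Z1)
  expect_equal(got$mean, ora$mean, tolerance = 1e-10)
  expect_equal(got$sd, ora$sd, tolerance = 1e-10)

  ## fixed 10 x 7 random design with standardisation and ML fit
  set.seed(31)
  X <- matrix(runif(10 * 7), 10, 7)
  y <- X %*% runif(7) + sin(3 * X[, 1]) * 0.3
  gp2 <- gp_emulator(X, drop(y), restarts = 3)
  Z2 <- matrix(runif(5 * 7), 5, 7)
  got2 <- predict(gp2, Z2)
  ora2 <- oracle_gp_predict(gp2, Z2)
  expect_equal(got2$mean, ora2$mean, tolerance = 1e-10)
  expect_equal(got2$sd, ora2$sd, tolerance = 1e-10)

  ## mean-uncertainty (universal kriging) variant agrees too
  got3 <- predict(gp2, Z2, mean_uncertainty = TRUE)
  ora3 <- oracle_gp_predict(gp2, Z2, mean_uncertainty = TRUE)
  expect_equal(got3$sd, ora3$sd, tolerance = 1e-10)
})

test_that("posterior interpolates the data and reverts to the prior", {
  set.seed(5)
  X <- matrix(runif(8, 0, 2))
  y <- sin(2 * X[, 1]) + 0.5
  gp <- gp_emulator(X, y, hyper = list(sigma = 1, phi = 0.5),
                    standardize = FALSE, nugget_rel = 1e-10)
  at_train <- predict(gp, X)
  expect_true(all(abs(at_train$mean - y) < 1e-5))
  expect_true(all(at_train$sd^2 <= 1e-6 * gp$sigma^2))

  far <- matrix(50)  # >= 20 lengthscales from every training point
  pr <- predict(gp, far)
  mu_far <- drop(cbind(1, 50) %*% gp$beta)
  expect_equal(pr$mean, mu_far, tolerance = 1e-6 * max(1, abs(mu_far)))
  expect_equal(pr$sd^2, gp$sigma^2, tolerance = 1e-6 * gp$sigma^2)
})

test_that("a linear response is reproduced exactly through the mean", {
  set.seed(77)
  X <- matrix(runif(12 * 2), 12, 2)
  y <- drop(2 + X %*% c(1.5, -0.7))
  gp <- gp_emulator(X, y, restarts = 2)
  Z <- matrix(runif(20 * 2, -0.5, 1.5), 20, 2)
  pr <- predict(gp, Z)
  expect_equal(pr$mean, drop(2 + Z %*% c(1.5, -0.7)), tolerance = 1e-6)
})

test_that("fits are deterministic given the optimisation seed", {
  set.seed(3)
  X <- matrix(runif(9 * 2), 9, 2)
  y <- drop(sin(2 * X[, 1]) + X[, 2])
  a <- gp_emulator(X, y, restarts = 4, opt_seed = 7)
  b <- gp_emulator(X, y, restarts = 4, opt_seed = 7)
  expect_identical(a$sigma, b$sigma)
  expect_identical(a$phi, b$phi)
  expect_identical(a$beta, b$beta)
})

test_that("standardisation is transparent: affine input/output maps undo", {
  set.seed(11)
  X <- matrix(runif(10 * 2), 10, 2)
  y <- drop(sin(3 * X[, 1]) + X[, 2]^2)
  gp0 <- gp_emulator(X, y, restarts = 3)
  ## shift/scale the inputs and outputs; the standardising fit must give
  ## the same predictions after mapping new points the same way
  A <- c(3, 0.2); b0 <- c(-5, 7)
  Xs <- sweep(sweep(X, 2, A, "*"), 2, b0, "+")
  ys <- 10 * y - 4
  gps <- gp_emulator(Xs, ys, restarts = 3)
  Z <- matrix(runif(6 * 2), 6, 2)
  Zs <- sweep(sweep(Z, 2, A, "*"), 2, b0, "+")
  p0 <- predict(gp0, Z)
  ps <- predict(gps, Zs)
  expect_equal(ps$mean, 10 * p0$mean - 4, tolerance = 1e-6)
  expect_equal(ps$sd, 10 * p0$sd, tolerance = 1e-6)
})

test_that("conditioning on an extra point never inflates the variance", {
  set.seed(21)
  for (rep in 1:4) {
    X <- matrix(runif(7), 7, 1)
    y <- rnorm(7)
    hyper <- list(sigma = 1, phi = runif(1, 0.3, 1))
    gp_small <- gp_emulator(X[1:6, , drop = FALSE], y[1:6], hyper = hyper,
                            standardize = FALSE, nugget_rel = 1e-8)
    gp_big <- gp_emulator(X, y, hyper = hyper, standardize = FALSE,
                          nugget_rel = 1e-8)
    Z <- matrix(runif(15), 15, 1)
    expect_true(all(predict(gp_big, Z)$sd <=
                      predict(gp_small, Z)$sd + 1e-8))
  }
})

test_that("posterior samples honour seed and degenerate at training points", {
  set.seed(13)
  X <- matrix(runif(6, 0, 2))
  y <- cos(X[, 1])
  gp <- gp_emulator(X, y, hyper = list(sigma = 1, phi = 0.6),
                    standardize = FALSE, nugget_rel = 1e-10)
  s1 <- simulate(gp, nsim = 5, seed = 99, newdata = X)
  s2 <- simulate(gp, nsim = 5, seed = 99, newdata = X)
  expect_identical(s1, s2)
  expect_true(all(abs(s1 - y) < 1e-3))
})

test_that("prior sample moments match the closed form", {
  grid <- seq(0, 5, length.out = 40)
  paths <- gp_prior_sample(grid, sigma = 1.3, phi = 1, mean = 2,
                           nsim = 2000, seed = 17)
  expect_equal(dim(paths), c(40, 2000))
  ## MC mean within 3 sigma / sqrt(nsim) of the prior mean, per point
  tol <- 3 * 1.3 / sqrt(2000)
  expect_true(all(abs(rowMeans(paths) - 2) < tol))
  sd_emp <- apply(paths, 1, sd)
  expect_true(all(abs(sd_emp - 1.3) < 0.12))
})

test_that("ML recovers known hyperparameters at n = 200, d = 1", {
  sigma0 <- 1.5; phi0 <- 0.8
  ok <- vapply(1:20, function(rep) {
    X <- with_seed(1000 + rep, matrix(sort(runif(200, 0, 10))))
    K <- .sqexp_cov(X, X, sigma0, phi0) + diag(1e-8, 200)
    y <- with_seed(2000 + rep,
                   drop(crossprod(chol(K), rnorm(200))))
    gp <- gp_emulator(X, y, restarts = 3, standardize = FALSE)
    abs(log(gp$sigma) - log(sigma0)) <= 0.5 &&
      abs(log(gp$phi) - log(phi0)) <= 0.5
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("refit-mode LOO equals explicit per-fold fit-and-predict", {
  set.seed(19)
  X <- matrix(runif(10 * 3), 10, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + 0.3 * sin(4 * X[, 1])
  gp <- gp_emulator(X, y, restarts = 3)
  rep_loo <- gp_loo(gp, mode = "refit")
  for (i in seq_len(10)) {
    fit_i <- gp_emulator(X[-i, , drop = FALSE], y[-i], restarts = 3)
    pr <- predict(fit_i, X[i, , drop = FALSE], mean_uncertainty = TRUE)
    expect_equal(rep_loo$table$mean[i], pr$mean, tolerance = 1e-10)
    expect_equal(rep_loo$table$sd[i], pr$sd, tolerance = 1e-10)
  }
  expect_equal(rep_loo$mse_loo,
               mean((rep_loo$table$mean - y)^2), tolerance = 1e-12)
  expect_equal(rep_loo$mse_rel_pct,
               100 * rep_loo$mse_loo / mean(y), tolerance = 1e-12)
})

test_that("LOO error vanishes for a response the mean represents", {
  set.seed(23)
  X <- matrix(runif(12 * 2), 12, 2)
  y <- drop(1 + X %*% c(2, -1))
  rep_loo <- gp_loo(gp_emulator(X, y, restarts = 2), mode = "refit")
  expect_lt(rep_loo$mse_loo, 1e-10)
})

test_that("LOO preconditions and residual methods are consistent", {
  set.seed(29)
  X <- matrix(runif(9 * 7), 9, 7)
  y <- rnorm(9)
  expect_error(gp_loo(gp_emulator(X, y, restarts = 1)), "n >= d \\+ 3")

  X2 <- matrix(runif(12 * 2), 12, 2)
  y2 <- drop(sin(3 * X2[, 1])) + X2[, 2]
  gp <- gp_emulator(X2, y2, restarts = 2)
  r_tr <- residuals(gp)
  expect_true(all(abs(r_tr) < 1e-4))
  r_loo <- residuals(gp, type = "loo")
  expect_equal(r_loo, y2 - gp_loo(gp, mode = "fixed")$table$mean,
               tolerance = 1e-12)
})
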