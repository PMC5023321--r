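# GP regression: oracle equivalence, hyperparameter recovery, predictive
# behaviour at interpolation and extrapolation limits.

test_that("posterior mean, variance and marginal likelihood match the dense oracle", {
  set.seed(7)
  for (rep in 1:3) {
    n <- sample(4:10, 1)
    X <- matrix(runif(n * 2), n, 2)
    y <- cos(2 * X[, 1]) + 0.5 * X[, 2] + rnorm(n, sd = 0.2)
    m <- fitGP(X, y, seed = rep, restarts = 1, maxit = 50)
    Xq <- matrix(runif(6), 3, 2)
    pr <- predict(m, Xq)
    or <- oracleGPPredict(m, Xq)
    expect_equal(pr$mean, or$mean, tolerance = 1e-8)
    expect_equal(pr$variance, or$variance, tolerance = 1e-8)
    expect_equal(logMarginalLikelihood(m), or$logLik, tolerance = 1e-8)
  }
})

test_that("single zero observation with unit prior variance has standard-normal density", {
  # log N(0; 0, 1) = -log(2*pi)/2; built directly, no optimisation
  m <- gpModel(ardKernel(1, signalVariance = 0.5), noiseVariance = 0.5,
               X = matrix(0, 1, 1), y = 0)
  expect_equal(logMarginalLikelihood(m), -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("rescaling y and variances by c^2 shifts the likelihood by -n log|c|", {
  set.seed(3)
  X <- matrix(runif(8), 8, 1)
  y <- rnorm(8)
  k1 <- ardKernel(0.7, signalVariance = 1.2)
  m1 <- gpModel(k1, noiseVariance = 0.4, X = X, y = y)
  cc <- 3.7
  k2 <- ardKernel(0.7, signalVariance = 1.2 * cc^2)
  m2 <- gpModel(k2, noiseVariance = 0.4 * cc^2, X = X, y = y * cc)
  expect_equal(logMarginalLikelihood(m2),
               logMarginalLikelihood(m1) - 8 * log(cc), tolerance = 1e-9)
})

test_that("noiseless linear function is recovered at interior points", {
  set.seed(21)
  X <- matrix(sort(runif(40)), 40, 1)
  y <- 2 * X[, 1] + 1
  m <- fitGP(X, y, seed = 1, restarts = 2)
  Xq <- matrix(c(0.3, 0.5, 0.7), 3, 1)
  pr <- predict(m, Xq)
  expect_equal(pr$mean, 2 * c(0.3, 0.5, 0.7) + 1, tolerance = 0.01)
})

test_that("noise variance is recovered within sampling tolerance at n = 500", {
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(runif(500), 500, 1)
    y <- sin(2 * pi * X[, 1]) + rnorm(500, sd = 1)
    m <- fitGP(X, y, seed = s, restarts = 0, maxit = 50)
    m@noiseVariance
  }, numeric(1))
  expect_true(all(ratios >= 0.8 & ratios <= 1.25))
})

test_that("irrelevant covariates get length-scales at least 5x the relevant one", {
  set.seed(5)
  n <- 300
  X <- matrix(runif(2 * n), n, 2)
  y <- sin(4 * X[, 1]) + rnorm(n, sd = 0.2)
  m <- fitGP(X, y, seed = 2, restarts = 2)
  ls <- m@kernel@lengthScales
  expect_gt(ls[2] / ls[1], 5)
})

test_that("predictions revert to the prior far from the data", {
  set.seed(8)
  X <- matrix(runif(25), 25, 1)
  y <- X[, 1] + rnorm(25, sd = 0.3)
  m <- fitGP(X, y, seed = 1, restarts = 1)
  far <- matrix(25 * max(m@kernel@lengthScales) * m@xScale + 100, 1, 1)
  pr <- predict(m, far)
  expect_equal(pr$mean, m@yCenter, tolerance = 1e-6)
  expect_equal(pr$variance, m@kernel@signalVariance, tolerance = 1e-6)
})

test_that("near-zero noise interpolates the training targets", {
  set.seed(10)
  X <- matrix(seq(0, 1, length.out = 8), 8, 1)
  y <- sin(3 * X[, 1])
  m <- gpModel(ardKernel(0.5, signalVariance = 1), noiseVariance = 1e-12,
               X = X, y = y)
  pr <- predict(m, X)
  expect_equal(pr$mean, y, tolerance = 1e-6)
})

test_that("function variance never increases when a duplicate observation is added", {
  set.seed(12)
  X <- matrix(runif(15), 15, 1)
  y <- cos(2 * X[, 1]) + rnorm(15, sd = 0.2)
  k <- ardKernel(0.4, signalVariance = 1)
  m1 <- gpModel(k, 0.05, X, y)
  m2 <- gpModel(k, 0.05, rbind(X, X[3, , drop = FALSE]), c(y, y[3]))
  Xq <- matrix(seq(0, 1, length.out = 20), 20, 1)
  expect_true(all(predict(m2, Xq)$variance <=
                  predict(m1, Xq)$variance + 1e-10))
})

test_that("held-out standardized residuals are calibrated under the prior", {
  # data simulated from the GP prior itself; KS test at alpha = .01
  passed <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 45
    X <- matrix(runif(n), n, 1)
    k <- ardKernel(0.3, signalVariance = 1)
    K <- kernelMatrix(k, X) + diag(0.2, n)
    y <- drop(rnorm(n) %*% chol(K))
    m <- fitGP(X[1:30, , drop = FALSE], y[1:30], seed = s, restarts = 1)
    pr <- predict(m, X[31:45, , drop = FALSE])
    z <- (y[31:45] - pr$mean) / sqrt(pr$variance + m@noiseVariance)
    suppressWarnings(ks.test(z, "pnorm")$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(passed), 0.95)
})

test_that("results are deterministic given the seed and stable under jitter", {
  set.seed(14)
  X <- matrix(runif(30), 30, 1)
  y <- sin(5 * X[, 1]) + rnorm(30, sd = 0.3)
  m1 <- fitGP(X, y, seed = 99, restarts = 3)
  m2 <- fitGP(X, y, seed = 99, restarts = 3)
  expect_identical(m1@kernel@lengthScales, m2@kernel@lengthScales)
  expect_identical(m1@logLik, m2@logLik)
  # moving one step up the jitter ladder changes means by < 1e-6
  mj <- m1
  K <- kernelMatrix(m1@kernel, m1@X)
  diag(K) <- diag(K) + m1@noiseVariance + 1e-9
  R <- chol(K)
  mj@chol <- R
  mj@alpha <- backsolve(R, backsolve(R, m1@y, transpose = TRUE))
  Xq <- matrix(runif(10), 10, 1)
  expect_lt(max(abs(predict(mj, Xq)$mean - predict(m1, Xq)$mean)), 1e-6)
})

test_that("degenerate and invalid inputs are rejected", {
  X <- matrix(runif(10), 10, 1)
  expect_error(fitGP(X, rep(2, 10), seed = 1), class = "npmapDegenerateResponse")
  expect_error(fitGP(X[1:2, , drop = FALSE], 1:2, seed = 1), "at least 3")
  expect_error(fitGP(X, c(rnorm(9), NA), seed = 1), "non-finite")
  m <- fitGP(X, rnorm(10), seed = 1, restarts = 0)
  expect_error(predict(m, matrix(1, 1, 2)), "covariates")
})
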