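# Mass-univariate estimation engine: NPM formula, SMSE, leakage guards,
# permutation equivariance, centile geometry.

test_that("NPM Z-scores apply the deviation formula exactly", {
  Y <- matrix(c(1, 2, 3, 4), 2, 2)
  mu <- matrix(c(1, 1, 1, 2), 2, 2)
  expect_equal(computeNPM(Y, mu, matrix(0.5, 2, 2), c(0.5, 0.5)),
               (Y - mu) / 1)
  # noise-only denominator
  expect_equal(computeNPM(matrix(2), matrix(0), matrix(0), 4)[1, 1], 1)
  expect_error(computeNPM(matrix(1), matrix(0), matrix(0), 0),
               "non-positive total variance")
  expect_error(computeNPM(matrix(1), matrix(0), matrix(0, 2, 2), 1),
               "identical shapes")
})

test_that("SMSE matches direct arithmetic and its edge cases", {
  expect_equal(smse(1:5, 1:5, var(1:5)), 0)
  y <- c(2, 4, 1, 7, 6)
  expect_equal(smse(y, rep(mean(y), 5), var(y)), mean((y - mean(y))^2) / var(y))
  pred <- c(2.2, 3.5, 1.4, 6.1, 6.3)
  expect_equal(smse(y, pred, 2.5), mean((y - pred)^2) / 2.5)
  expect_error(smse(1:4, 1:3, 1), "equal length")
  expect_error(smse(1:4, 2:5, 0), "baselineVariance")
})

test_that("duplicated location columns fit identically and subject order does not matter", {
  cohort <- makeTinyCohort(n = 24, p = 2, seed = 6)
  Y <- responses(cohort)
  Y2 <- cbind(Y, dup = Y[, 1])
  colnames(Y2) <- c("L01", "L02", "dup")
  c2 <- NormativeCohort(Y2, covariates(cohort))
  fit <- estimateNormative(c2, k = 3, seed = 4, restarts = 1,
                           finalModels = FALSE)
  z <- npm(fit)
  expect_identical(z[, "L01"], setNames(z[, "dup"], names(z[, "L01"])))

  # joint permutation of subjects permutes outputs and nothing else
  perm <- sample(24)
  c3 <- NormativeCohort(Y2[perm, ], covariates(cohort)[perm, ],
                        subjectIds = rownames(Y2)[perm])
  fit3 <- estimateNormative(c3, k = 3, folds = foldAssignment(fit)[perm],
                            seed = 4, restarts = 1, finalModels = FALSE)
  expect_equal(npm(fit3), z[perm, ], tolerance = 1e-10)
})

test_that("held-out predictions ignore the held-out fold's responses", {
  cohort <- makeTinyCohort(n = 30, p = 3, seed = 9)
  fit <- estimateNormative(cohort, k = 3, seed = 2, restarts = 1,
                           finalModels = FALSE)
  f1 <- foldAssignment(fit) == 1
  Y <- responses(cohort)
  Y[f1, 2] <- Y[f1, 2] + 100  # corrupt fold 1 at one location
  c2 <- NormativeCohort(Y, covariates(cohort))
  fit2 <- estimateNormative(c2, k = 3, folds = foldAssignment(fit), seed = 2,
                            restarts = 1, finalModels = FALSE)
  # fold-1 predictions are bit-identical with or without the corruption
  m1 <- t(SummarizedExperiment::assay(fit, "cvMean"))
  m2 <- t(SummarizedExperiment::assay(fit2, "cvMean"))
  expect_identical(m1[f1, 2], m2[f1, 2])
  v1 <- t(SummarizedExperiment::assay(fit, "cvVar"))
  v2 <- t(SummarizedExperiment::assay(fit2, "cvVar"))
  expect_identical(v1[f1, 2], v2[f1, 2])
})

test_that("SMSE separates signal from noise locations", {
  set.seed(17)
  n <- 80
  X <- cbind(runif(n))
  Y <- cbind(sig = sin(4 * X[, 1]) * 1.5 + rnorm(n, sd = 0.5),
             noise = rnorm(n))
  rownames(X) <- rownames(Y) <- sprintf("S%02d", 1:n)
  fit <- estimateNormative(NormativeCohort(Y, X), k = 4, seed = 3,
                           restarts = 1, finalModels = FALSE)
  sm <- setNames(SummarizedExperiment::rowData(fit)$smse, rownames(fit))
  expect_lt(sm["sig"], 1)
  expect_gt(sm["noise"], 0.8)
  expect_lt(sm["noise"], 1.3)
})

test_that("centile surfaces pass through the mean and never cross", {
  cohort <- makeTinyCohort(n = 40, p = 2, seed = 30)
  fit <- estimateNormative(cohort, k = 4, seed = 1, restarts = 1,
                           finalModels = TRUE)
  grid <- cbind(seq(0, 1, length.out = 100), 0.5)
  cs <- centileSurface(fit, grid, centiles = c(0.025, 0.25, 0.5, 0.75, 0.975))
  pr <- predictCohort(fit, grid)
  for (j in 1:2) {
    surf <- cs[[j]]
    expect_equal(surf[, "c0.5"], pr$mean[, j], tolerance = 1e-12)
    # symmetric band width = 2 * z_{.975} * sd
    sdTot <- sqrt(pr$variance[, j] + pr$noiseVariance[j])
    expect_equal(surf[, "c0.975"] - surf[, "c0.025"],
                 2 * qnorm(0.975) * sdTot, tolerance = 1e-6)
    expect_true(all(diff(t(surf)) > 0))  # nested centiles in order
  }
  expect_error(centileSurface(fit, grid, centiles = c(0, 0.5)), "inside")
})

test_that("principal-axis anchors move monotonically away from the baseline", {
  set.seed(3)
  X <- cbind(runif(100, 0, 1), runif(100, 0, 1) * 0.5 + 0.2)
  anchors <- principalAxisAnchors(X, n = 5)
  expect_equal(dim(anchors), c(5, 2))
  v <- eigen(cov(X))$vectors[, 1]
  proj <- anchors %*% v
  expect_true(all(diff(proj) < 0) || all(diff(proj) > 0))
})

test_that("cross-validated null cohort yields calibrated residual moments", {
  set.seed(44)
  n <- 120
  X <- cbind(runif(n))
  k <- ardKernel(0.4, signalVariance = 1)
  K <- kernelMatrix(k, X) + diag(0.5, n)
  Y <- cbind(drop(rnorm(n) %*% chol(K)))
  rownames(X) <- rownames(Y) <- sprintf("S%03d", 1:n)
  fit <- estimateNormative(NormativeCohort(Y, X), k = 4, seed = 5,
                           restarts = 1, finalModels = FALSE)
  z <- as.numeric(npm(fit))
  expect_lt(abs(mean(z)), 0.12)
  expect_gt(var(z), 0.75)
  expect_lt(var(z), 1.25)
})
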