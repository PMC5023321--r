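# Synthetic cohort generator: determinism, planted structure, symptom
# mechanisms.

test_that("the same spec and seed reproduce the cohort bit for bit", {
  spec <- cohortSpec(nSubjects = 25, nLocations = 30, seed = 12,
                     outlierFraction = 0.1, symptomModel = "mixture")
  s1 <- simulateCohort(spec)
  s2 <- simulateCohort(spec)
  expect_identical(responses(s1$cohort), responses(s2$cohort))
  expect_identical(covariates(s1$cohort), covariates(s2$cohort))
  expect_identical(symptomScores(s1$cohort), symptomScores(s2$cohort))
  expect_identical(s1$truth$outlierMagnitudes, s2$truth$outlierMagnitudes)
  s3 <- simulateCohort(cohortSpec(nSubjects = 25, nLocations = 30, seed = 13))
  expect_false(identical(responses(s1$cohort), responses(s3$cohort)))
})

test_that("covariates are bounded and skewed like AUC scores", {
  sim <- simulateCohort(cohortSpec(nSubjects = 400, nLocations = 1, seed = 2))
  X <- covariates(sim$cohort)
  expect_true(all(X >= 0 & X <= 1))
  expect_lt(mean(X[, "aucSmall"]), mean(X[, "aucLarge"]))  # small rewards discounted more
  expect_gt(cor(X[, 1], X[, 2]), 0.2)
})

test_that("family sizes stay within 1-3 and share a fold after grouping", {
  sim <- simulateCohort(cohortSpec(nSubjects = 60, nLocations = 2, seed = 5))
  fams <- familyIds(sim$cohort)
  expect_true(all(table(fams) <= 3))
  f <- groupedKFold(fams, k = 5, seed = 1)
  for (fam in unique(fams)) expect_length(unique(f[fams == fam]), 1)
})

test_that("planted outliers separate from the rest in absolute deviance", {
  seps <- vapply(1:20, function(s) {
    sim <- simulateCohort(cohortSpec(nSubjects = 60, nLocations = 400,
                                     seed = s, outlierFraction = 0.05,
                                     outlierMagnitude = 4))
    Y <- responses(sim$cohort)
    z <- scale(Y)  # marginal Z against the cohort, cheap stand-in for NPM
    d <- summarizeDeviance(z, modes = "absolute")$absolute
    planted <- rownames(Y) %in% sim$truth$outlierSubjects
    mean(d[planted]) > mean(d[!planted])
  }, logical(1))
  expect_true(all(seps))
})

test_that("infeasible specs are rejected", {
  expect_error(cohortSpec(nLocations = 10, outlierNLocations = 11), "exceeds")
  expect_error(cohortSpec(outlierFraction = 1.2), "fractions")
  expect_error(cohortSpec(noiseSd = 0), "positive")
})

test_that("symptom mechanisms act on the intended subpopulations", {
  spec <- cohortSpec(nSubjects = 300, nLocations = 10, seed = 8,
                     outlierFraction = 0.1, outlierMagnitudeSpread = 2,
                     symptomModel = "deviance-linked")
  sim <- simulateCohort(spec)
  sym <- symptomScores(sim$cohort)
  planted <- colnames(sim$cohort) %in% sim$truth$outlierSubjects
  # symptoms track injected magnitude among outliers
  expect_gt(cor(sym[planted], sim$truth$outlierMagnitudes), 0.5)
  # extreme-of-normal ties symptoms to covariate axis position instead
  sim2 <- simulateCohort(cohortSpec(nSubjects = 300, nLocations = 10,
                                    seed = 8, outlierFraction = 0,
                                    symptomModel = "extreme-of-normal"))
  X <- covariates(sim2$cohort)
  proj <- scale(X) %*% eigen(cov(scale(X)))$vectors[, 1]
  expect_gt(abs(cor(symptomScores(sim2$cohort), proj)), 0.3)
})
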