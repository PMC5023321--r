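# Synthetic cohorts with the structure the normative method assumes:
# bounded skewed covariates, smooth nonlinear covariate->response surfaces at
# a subset of locations, per-location Gaussian noise, family-shared random
# intercepts, planted outlier subjects and configurable symptom mechanisms.

#' Specify a synthetic cohort
#'
#' Collects and validates the parameters of [simulateCohort()]. Defaults
#' describe the reference desk-scale cohort: 500 subjects x 2000 locations,
#' two correlated bounded covariates resembling delay-discounting AUC scores
#' at two reward magnitudes, 30% of locations carrying smooth covariate
#' signal of unit standard deviation against unit-SD noise, families of size
#' 1-3 sharing a random intercept, and 5% planted outlier subjects deviating
#' by 4 total SD at 1% of locations.
#'
#' @param nSubjects,nCovariates,nLocations Cohort dimensions.
#' @param signalFraction Fraction of locations whose mean depends on the
#'   covariates.
#' @param signalSd Standard deviation of the covariate-driven surface at
#'   signal locations (response units).
#' @param noiseSd Observation noise SD; scalar or per-location vector.
#' @param familySizeProbs Probabilities of family sizes 1, 2, 3.
#' @param familyEffectSd SD of the per-family, per-location shared random
#'   intercept (0 disables family correlation).
#' @param outlierFraction Fraction of subjects receiving planted deviations.
#' @param outlierNLocations Number of deviant locations per outlier subject.
#' @param outlierMagnitude Planted deviation size, in SD units of the
#'   location's total normative variation.
#' @param outlierMagnitudeSpread Scale of a heavy-tailed (Pareto, shape 1.5)
#'   spread added to `outlierMagnitude` per outlier subject (0 = constant
#'   magnitude). A heavy-tailed spread keeps the most extreme subjects
#'   distinguishable, which is what makes tail correlations estimable in
#'   the top percentiles.
#' @param outlierSign Direction of planted deviations.
#' @param symptomModel Symptom generation mechanism: `"null"` (baseline
#'   only), `"extreme-of-normal"` (symptoms track the subject's position
#'   along the covariate principal axis), `"deviance-linked"` (symptoms
#'   track the injected deviation magnitude of outlier subjects), or
#'   `"mixture"` (both mechanisms in different subpopulations).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec.
#' @return A validated list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(nSubjects = 500, nCovariates = 2, nLocations = 2000,
                       signalFraction = 0.3, signalSd = 1, noiseSd = 1,
                       familySizeProbs = c(0.5, 0.3, 0.2),
                       familyEffectSd = 0.3,
                       outlierFraction = 0.05,
                       outlierNLocations = ceiling(0.01 * nLocations),
                       outlierMagnitude = 4, outlierMagnitudeSpread = 0,
                       outlierSign = c("mixed", "positive", "negative"),
                       symptomModel = c("null", "extreme-of-normal",
                                        "deviance-linked", "mixture"),
                       seed = 1) {
  spec <- list(
    nSubjects = as.integer(nSubjects), nCovariates = as.integer(nCovariates),
    nLocations = as.integer(nLocations),
    signalFraction = signalFraction, signalSd = signalSd, noiseSd = noiseSd,
    familySizeProbs = familySizeProbs / sum(familySizeProbs),
    familyEffectSd = familyEffectSd,
    outlierFraction = outlierFraction,
    outlierNLocations = as.integer(outlierNLocations),
    outlierMagnitude = outlierMagnitude,
    outlierMagnitudeSpread = outlierMagnitudeSpread,
    outlierSign = match.arg(outlierSign),
    symptomModel = match.arg(symptomModel),
    seed = as.integer(seed))
  with(spec, {
    if (nSubjects < 2 || nCovariates < 1 || nLocations < 1)
      stop("cohort dimensions must be positive (>= 2 subjects)")
    for (f in c(signalFraction, outlierFraction))
      if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
    if (outlierNLocations > nLocations)
      stop("outlierNLocations (", outlierNLocations,
           ") exceeds nLocations (", nLocations, ")")
    if (any(noiseSd <= 0)) stop("noiseSd must be positive")
    if (length(familySizeProbs) != 3) stop("familySizeProbs must have 3 entries")
  })
  structure(spec, class = "CohortSpec")
}

# Covariates: correlated Beta draws mimicking bounded, skewed AUC scores
# (small-reward AUC skewed low, large-reward AUC more symmetric).
.simCovariates <- function(n, d) {
  shapes <- rbind(c(1.2, 3.8), c(2.0, 2.35))
  L <- chol(matrix(0.5, 2, 2) + diag(0.5, 2))
  X <- matrix(NA_real_, n, d)
  for (k in seq_len(d)) {
    if (k <= 2) next
    X[, k] <- rbeta(n, 2, 2)
  }
  Z <- matrix(rnorm(n * 2), n, 2) %*% L
  U <- pnorm(Z)
  X[, 1] <- stats::qbeta(U[, 1], shapes[1, 1], shapes[1, 2])
  if (d >= 2) X[, 2] <- stats::qbeta(U[, 2], shapes[2, 1], shapes[2, 2])
  colnames(X) <- c("aucSmall", "aucLarge", if (d > 2) paste0("x", 3:d))[seq_len(d)]
  X
}

# Smooth low-order polynomial surface with random weights, rescaled to a
# target SD over the cohort.
.simSurface <- function(Xc, targetSd) {
  B <- cbind(Xc, Xc^2, if (ncol(Xc) >= 2) Xc[, 1] * Xc[, 2])
  w <- rnorm(ncol(B))
  f <- as.numeric(B %*% w)
  s <- sd(f)
  if (s > 0) f <- f * (targetSd / s)
  list(values = f, weights = w)
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec A [cohortSpec()]; additional arguments override its fields.
#' @param ... Fields passed to [cohortSpec()] when `spec` is missing.
#' @return A list with elements `cohort` (a [NormativeCohort-class] carrying
#'   covariates, responses, family labels and symptoms) and `truth` (signal
#'   locations and surface weights, noise SDs, outlier subjects with their
#'   deviant locations, signs and injected magnitudes, and the symptom
#'   generation parameters).
#' @examples
#' sim <- simulateCohort(cohortSpec(nSubjects = 20, nLocations = 50, seed = 3))
#' sim$cohort
#' @export
simulateCohort <- function(spec = cohortSpec(...), ...) {
  stopifnot(inherits(spec, "CohortSpec"))
  .withSeed(spec$seed, .simulateCohortImpl(spec))
}

.simulateCohortImpl <- function(spec) {
  n <- spec$nSubjects; p <- spec$nLocations; d <- spec$nCovariates

  X <- .simCovariates(n, d)
  Xc <- scale(X)

  # family structure
  fams <- integer(0)
  fid <- 0L
  while (length(fams) < n) {
    fid <- fid + 1L
    sz <- sample.int(3L, 1L, prob = spec$familySizeProbs)
    fams <- c(fams, rep(fid, sz))
  }
  fams <- fams[seq_len(n)]
  familyIds <- paste0("F", fams)

  noiseSd <- rep(spec$noiseSd, length.out = p)
  nSignal <- round(spec$signalFraction * p)
  signalLoc <- sort(sample.int(p, nSignal))
  surfaces <- vector("list", p)
  Y <- matrix(0, n, p)
  for (j in signalLoc) {
    s <- .simSurface(Xc, spec$signalSd)
    surfaces[[j]] <- s$weights
    Y[, j] <- s$values
  }
  # family random intercepts (per family, per location)
  if (spec$familyEffectSd > 0) {
    nf <- max(fams)
    Fe <- matrix(rnorm(nf * p, sd = spec$familyEffectSd), nf, p)
    Y <- Y + Fe[fams, , drop = FALSE]
  }
  Y <- Y + sweep(matrix(rnorm(n * p), n, p), 2, noiseSd, "*")

  # planted outliers, shifted by magnitude x empirical total SD
  nOut <- round(spec$outlierFraction * n)
  outliers <- if (nOut > 0) sort(sample.int(n, nOut)) else integer(0)
  totalSd <- apply(Y, 2, sd)
  outLocs <- list(); outMag <- numeric(0); outSign <- integer(0)
  if (nOut > 0) {
    # heavy-tailed (Pareto, shape 1.5) magnitude spread: keeps the top
    # order statistics mutually spread out, so the most extreme subjects
    # remain distinguishable — exponential-tail spacings collapse too often
    outMag <- spec$outlierMagnitude +
      (if (spec$outlierMagnitudeSpread > 0)
         spec$outlierMagnitudeSpread * (runif(nOut)^(-1 / 1.5) - 1)
       else rep(0, nOut))
    outSign <- switch(spec$outlierSign,
      positive = rep(1L, nOut),
      negative = rep(-1L, nOut),
      mixed = sample(c(-1L, 1L), nOut, replace = TRUE))
    outLocs <- lapply(seq_len(nOut), function(i)
      sort(sample.int(p, spec$outlierNLocations)))
    for (i in seq_len(nOut)) {
      jj <- outLocs[[i]]
      Y[outliers[i], jj] <- Y[outliers[i], jj] +
        outSign[i] * outMag[i] * totalSd[jj]
    }
  }

  # symptoms
  base <- rgamma(n, shape = 2, scale = 1.2)
  proj <- as.numeric(Xc %*% eigen(stats::cov(Xc))$vectors[, 1])
  if (stats::cor(proj, rowMeans(Xc)) > 0) proj <- -proj  # orient: higher = more discounting
  projZ <- as.numeric(scale(proj))
  enSlope <- 2; devSlope <- 2.5; devNoiseSd <- 0.5
  symptoms <- base
  applyEN <- spec$symptomModel %in% c("extreme-of-normal", "mixture")
  applyDev <- spec$symptomModel %in% c("deviance-linked", "mixture")
  if (applyEN) {
    who <- if (spec$symptomModel == "mixture") setdiff(seq_len(n), outliers)
           else seq_len(n)
    symptoms[who] <- symptoms[who] + enSlope * pmax(projZ[who], 0)
  }
  if (applyDev && nOut > 0) {
    # for deviance-linked subjects the abnormality mechanism dominates the
    # symptom: high baseline shifted by the injected magnitude with small
    # noise, so the symptom ranks these subjects by their deviation
    symptoms[outliers] <- unname(quantile(base, 0.75)) +
      devSlope * (outMag - spec$outlierMagnitude) +
      rnorm(nOut, sd = devNoiseSd)
  }

  subjectIds <- sprintf("S%04d", seq_len(n))
  locationIds <- sprintf("L%05d", seq_len(p))
  dimnames(Y) <- list(subjectIds, locationIds)
  rownames(X) <- subjectIds

  cohort <- NormativeCohort(Y, X, familyIds = familyIds, symptoms = symptoms,
                            subjectIds = subjectIds, locationIds = locationIds)
  truth <- list(
    spec = unclass(spec),
    signalLocations = locationIds[signalLoc],
    surfaceWeights = setNames(surfaces[signalLoc], locationIds[signalLoc]),
    noiseSd = setNames(noiseSd, locationIds),
    totalSd = setNames(totalSd, locationIds),
    outlierSubjects = subjectIds[outliers],
    outlierLocations = setNames(lapply(outLocs, function(j) locationIds[j]),
                                subjectIds[outliers]),
    outlierMagnitudes = setNames(outMag, subjectIds[outliers]),
    outlierSigns = setNames(outSign, subjectIds[outliers]),
    symptomParams = list(model = spec$symptomModel, baseShape = 2,
                         baseScale = 1.2, enSlope = enSlope,
                         devSlope = devSlope, devNoiseSd = devNoiseSd))
  list(cohort = cohort, truth = truth)
}
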