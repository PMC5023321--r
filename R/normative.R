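# Mass-univariate normative estimation under grouped cross-validation.

#' Estimate normative models across locations
#'
#' Fits an independent GP regression per response location. Held-out
#' predictions are produced under grouped k-fold cross-validation — for each
#' fold, models see only the training subjects, so no subject's response
#' leaks into its own prediction — and the resulting deviation Z-scores
#' (normative probability map) are stored alongside the predictions. A final
#' per-location model trained on all subjects is kept for centile charts and
#' transfer to new cohorts.
#'
#' Responses are centred and covariates standardised within each training
#' fold only. Per-location fit failures are flagged in `rowData` and their
#' assay entries set to `NA`; the run aborts if more than `maxFailFraction`
#' of locations fail.
#'
#' @param cohort A [NormativeCohort-class].
#' @param k Number of cross-validation folds (default 10).
#' @param folds Optional precomputed fold assignment from [groupedKFold()];
#'   overrides `k`.
#' @param seed Integer seed (fold shuffle and optimiser restarts).
#' @param variant Kernel variant, see [ardKernel()].
#' @param restarts Optimiser restarts per location fit.
#' @param maxit Optimiser iteration cap per restart.
#' @param finalModels Also fit per-location models on all subjects
#'   (needed for [centileSurface()] and [predictCohort()]).
#' @param maxFailFraction Abort threshold for the fraction of failed
#'   locations.
#' @return A [NormativeFit-class].
#' @seealso [npm()], [summarizeDeviance()], [computeNPM()]
#' @export
estimateNormative <- function(cohort, k = 10, folds = NULL, seed = 1,
                              variant = c("se-ard", "linear-se-ard"),
                              restarts = 2, maxit = 60, finalModels = TRUE,
                              maxFailFraction = 0.05) {
  variant <- match.arg(variant)
  stopifnot(is(cohort, "NormativeCohort"))
  X <- covariates(cohort)
  Y <- responses(cohort)
  n <- nrow(Y); p <- ncol(Y)
  if (is.null(folds)) {
    groups <- familyIds(cohort) %||% rownames(Y)
    folds <- groupedKFold(groups, k = k, seed = seed)
  }
  if (length(folds) != n) stop("fold assignment length must equal subjects")
  k <- max(folds)

  cvMean <- matrix(NA_real_, n, p)
  cvVar <- matrix(NA_real_, n, p)
  cvNoise <- matrix(NA_real_, n, p)
  smseFold <- matrix(NA_real_, k, p)
  failed <- logical(p)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    for (j in seq_len(p)) {
      if (failed[j]) next
      # one seed per fold (not per location): identical response columns
      # must yield identical fits
      fit <- tryCatch(
        fitGP(Xtr, Y[tr, j], variant = variant, restarts = restarts,
              seed = (seed * 97L + f * 131L) %% 2147483647L,
              maxit = maxit),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failed[j] <- TRUE
        next
      }
      pr <- predict(fit, Xte)
      cvMean[te, j] <- pr$mean
      cvVar[te, j] <- pr$variance
      cvNoise[te, j] <- fit@noiseVariance
      smseFold[f, j] <- smse(Y[te, j], pr$mean, var(Y[te, j]))
    }
  }
  cvMean[, failed] <- NA_real_
  cvVar[, failed] <- NA_real_
  cvNoise[, failed] <- NA_real_
  if (mean(failed) > maxFailFraction)
    stop(sum(failed), " of ", p, " locations failed to fit (> ",
         maxFailFraction * 100, "%)")

  z <- matrix(NA_real_, n, p)
  ok <- !failed
  z[, ok] <- computeNPM(Y[, ok, drop = FALSE], cvMean[, ok, drop = FALSE],
                        cvVar[, ok, drop = FALSE], cvNoise[, ok, drop = FALSE])

  models <- vector("list", p)
  finalNoise <- rep(NA_real_, p)
  finalLogLik <- rep(NA_real_, p)
  if (finalModels) {
    for (j in seq_len(p)) {
      if (failed[j]) next
      fit <- tryCatch(
        fitGP(X, Y[, j], variant = variant, restarts = restarts,
              seed = (seed * 97L) %% 2147483647L, maxit = maxit),
        error = function(e) NULL)
      if (is.null(fit)) { failed[j] <- TRUE; next }
      models[[j]] <- fit
      finalNoise[j] <- fit@noiseVariance
      finalLogLik[j] <- fit@logLik
    }
  }

  rd <- S4Vectors::DataFrame(
    smse = colMeans(smseFold, na.rm = TRUE),
    noiseVariance = finalNoise,
    logLik = finalLogLik,
    failed = failed,
    row.names = colnames(Y))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = t(z), cvMean = t(cvMean), cvVar = t(cvVar),
                  cvNoise = t(cvNoise), response = t(Y)),
    rowData = rd,
    colData = SummarizedExperiment::colData(cohort))
  S4Vectors::metadata(se) <- list(
    covariateNames = S4Vectors::metadata(cohort)$covariateNames,
    folds = folds,
    models = models,
    provenance = "cross-validated",
    config = list(k = k, variant = variant, restarts = restarts,
                  maxit = maxit, seed = seed))
  new("NormativeFit", se)
}

#' Compute normative probability map Z-scores
#'
#' Elementwise deviation Z-score combining the prediction error, the
#' held-out predictive (function) variance and the normative noise variance:
#' `z = (y - yhat) / sqrt(predVar + noiseVar)`.
#'
#' @param Y Observed responses (subjects x locations).
#' @param predMean,predVar Held-out predictive means and noise-free function
#'   variances, same shape as `Y`.
#' @param noiseVar Normative noise variance: matrix like `Y`, or a vector of
#'   per-location values recycled across subjects.
#' @return Matrix of Z-scores, same shape as `Y`.
#' @export
computeNPM <- function(Y, predMean, predVar, noiseVar) {
  Y <- as.matrix(Y); predMean <- as.matrix(predMean)
  predVar <- as.matrix(predVar)
  if (!all(dim(Y) == dim(predMean)) || !all(dim(Y) == dim(predVar)))
    stop("Y, predMean and predVar must have identical shapes")
  if (is.matrix(noiseVar)) {
    if (!all(dim(noiseVar) == dim(Y)))
      stop("noiseVar matrix must match the shape of Y")
    nv <- noiseVar
  } else {
    if (length(noiseVar) != ncol(Y))
      stop("noiseVar vector must have one entry per location")
    nv <- matrix(noiseVar, nrow(Y), ncol(Y), byrow = TRUE)
  }
  tot <- predVar + nv
  bad <- which(tot <= 0 & is.finite(tot), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive total variance at location(s) ",
         paste(unique(colnames(Y)[bad[, 2]] %||% bad[, 2]), collapse = ", "))
  (Y - predMean) / sqrt(tot)
}

#' Standardized mean squared error
#'
#' Mean squared prediction error divided by a baseline variance (typically
#' the variance of the test targets); values below 1 mean the model predicts
#' better than the training mean.
#'
#' @param true,predicted Numeric vectors of equal length (>= 2).
#' @param baselineVariance Positive baseline variance.
#' @return The SMSE as a scalar.
#' @examples
#' smse(1:5, c(1.1, 2, 2.9, 4, 5.2), var(1:5))
#' @export
smse <- function(true, predicted, baselineVariance) {
  if (length(true) != length(predicted) || length(true) < 2)
    stop("true and predicted must have equal length >= 2")
  if (!is.finite(baselineVariance) || baselineVariance <= 0)
    stop("baselineVariance must be > 0")
  mean((true - predicted)^2) / baselineVariance
}

#' @rdname npm
#' @export
setMethod("npm", "NormativeFit", function(object)
  t(SummarizedExperiment::assay(object, "z")))

#' @rdname foldAssignment
#' @export
setMethod("foldAssignment", "NormativeFit", function(object)
  S4Vectors::metadata(object)$folds)

#' @describeIn noiseVariance Per-location noise variances of the final
#'   (all-data) normative models.
#' @export
setMethod("noiseVariance", "NormativeFit", function(object)
  SummarizedExperiment::rowData(object)$noiseVariance)

#' @rdname cohort-accessors
#' @export
setMethod("responses", "NormativeFit", function(object)
  t(SummarizedExperiment::assay(object, "response")))

#' @rdname cohort-accessors
#' @export
setMethod("covariates", "NormativeFit", function(object) {
  covs <- S4Vectors::metadata(object)$covariateNames
  m <- as.matrix(as.data.frame(
    SummarizedExperiment::colData(object)[, covs, drop = FALSE]))
  rownames(m) <- colnames(object)
  m
})

#' @rdname cohort-accessors
#' @export
setMethod("symptomScores", "NormativeFit", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if ("symptom" %in% colnames(cd)) as.numeric(cd$symptom) else NULL
})

setMethod("show", "NormativeFit", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("NormativeFit: ", ncol(object), " subjects x ", nrow(object),
      " locations (k = ", S4Vectors::metadata(object)$config$k, " folds)\n",
      sep = "")
  cat("  median SMSE: ", signif(stats::median(rd$smse, na.rm = TRUE), 3),
      "; failed locations: ", sum(rd$failed), "\n", sep = "")
  z <- SummarizedExperiment::assay(object, "z")
  cat("  pooled Z: mean ", signif(mean(z, na.rm = TRUE), 3), ", variance ",
      signif(var(as.numeric(z), na.rm = TRUE), 3), "\n", sep = "")
})

#' Predict normative responses for new subjects
#'
#' Applies the final (all-data) per-location models of a fit to new
#' covariate rows, returning predictive means, function variances and the
#' per-location noise variances — the ingredients of a transfer-cohort NPM.
#'
#' @param fit A [NormativeFit-class] estimated with `finalModels = TRUE`.
#' @param X Matrix of new covariate rows.
#' @return List with matrices `mean` and `variance` (subjects x locations)
#'   and vector `noiseVariance` (per location).
#' @export
predictCohort <- function(fit, X) {
  stopifnot(is(fit, "NormativeFit"))
  models <- S4Vectors::metadata(fit)$models
  if (all(vapply(models, is.null, logical(1))))
    stop("fit has no final models; re-run estimateNormative(finalModels = TRUE)")
  X <- as.matrix(X)
  p <- length(models)
  mu <- matrix(NA_real_, nrow(X), p, dimnames = list(rownames(X), rownames(fit)))
  va <- matrix(NA_real_, nrow(X), p, dimnames = dimnames(mu))
  nv <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    if (is.null(models[[j]])) next
    pr <- predict(models[[j]], X)
    mu[, j] <- pr$mean
    va[, j] <- pr$variance
    nv[j] <- models[[j]]@noiseVariance
  }
  list(mean = mu, variance = va, noiseVariance = nv)
}

#' Centile surfaces of the normative model
#'
#' Evaluates predictive centile curves over a grid of covariate values:
#' centile `c` equals `mean + qnorm(c) * sqrt(functionVariance +
#' noiseVariance)`, the Gaussian predictive quantile, so nested centile
#' bands cannot cross.
#'
#' @param fit A [NormativeFit-class] with final models.
#' @param grid Matrix of covariate rows at which to evaluate the surfaces.
#' @param centiles Probabilities in (0, 1).
#' @param locations Location identifiers or indices (default: all
#'   non-failed locations).
#' @return A list, one element per location, each a grid-points x centiles
#'   matrix.
#' @export
centileSurface <- function(fit, grid, centiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                           locations = NULL) {
  if (any(centiles <= 0 | centiles >= 1))
    stop("centiles must lie strictly inside (0, 1)")
  models <- S4Vectors::metadata(fit)$models
  idx <- seq_along(models)
  if (!is.null(locations)) {
    idx <- if (is.character(locations)) match(locations, rownames(fit))
           else as.integer(locations)
  }
  grid <- as.matrix(grid)
  out <- lapply(idx, function(j) {
    m <- models[[j]]
    if (is.null(m)) return(NULL)
    pr <- predict(m, grid)
    sdTot <- sqrt(pr$variance + m@noiseVariance)
    surf <- outer(seq_len(nrow(grid)), seq_along(centiles),
                  function(i, c2) pr$mean[i] + qnorm(centiles[c2]) * sdTot[i])
    dimnames(surf) <- list(NULL, paste0("c", centiles))
    surf
  })
  names(out) <- rownames(fit)[idx]
  out
}

#' Anchor points along the principal covariate axis
#'
#' Places evenly spaced anchor points along the first principal axis of the
#' covariate cloud, measured from a baseline point — the device used to
#' visualise a normative surface at increasing overall severity.
#'
#' @param X Covariate matrix (subjects x covariates).
#' @param n Number of anchors.
#' @param baseline Baseline covariate row; default is the covariate-wise
#'   maximum projected onto the principal axis (a "no deviation" reference).
#' @return An `n` x `ncol(X)` matrix of covariate rows.
#' @export
principalAxisAnchors <- function(X, n = 5, baseline = NULL) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  v <- eigen(stats::cov(X))$vectors[, 1]
  proj <- as.numeric((X - matrix(ctr, nrow(X), ncol(X), byrow = TRUE)) %*% v)
  if (is.null(baseline)) baseline <- ctr + max(proj) * v
  bProj <- as.numeric((baseline - ctr) %*% v)
  steps <- seq(bProj, min(proj), length.out = n + 1)[-1]
  t(vapply(steps, function(s2) ctr + s2 * v, numeric(ncol(X))))
}
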