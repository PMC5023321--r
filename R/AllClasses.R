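#' @import methods
#' @importFrom stats optim pnorm qnorm rnorm runif rbeta rgamma rexp sd var
#'   p.adjust cor.test predict quantile ks.test ecdf setNames complete.cases
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom Rcpp evalCpp
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @useDynLib npmap, .registration = TRUE
NULL

#' Covariance kernel for Gaussian process regression
#'
#' A stationary squared-exponential kernel with one length-scale per covariate
#' (automatic relevance determination, ARD), optionally summed with a linear
#' kernel. Length-scales act as inverse relevance weights: a covariate with a
#' large length-scale has little influence on the fitted function.
#'
#' @slot variant Either `"se-ard"` (squared-exponential ARD) or
#'   `"linear-se-ard"` (linear kernel plus squared-exponential ARD).
#' @slot lengthScales Positive numeric vector, one entry per covariate, in
#'   covariate units.
#' @slot signalVariance Positive scalar, the marginal variance of the latent
#'   function (response units squared).
#' @slot linearVariance Non-negative scalar variance of the linear component
#'   (used only by the `"linear-se-ard"` variant).
#'
#' @seealso [ardKernel()], [kernelMatrix()]
#' @export
setClass("GPKernel",
  representation(
    variant = "character",
    lengthScales = "numeric",
    signalVariance = "numeric",
    linearVariance = "numeric"
  )
)

setValidity("GPKernel", function(object) {
  msg <- character()
  if (!object@variant %in% c("se-ard", "linear-se-ard"))
    msg <- c(msg, "variant must be 'se-ard' or 'linear-se-ard'")
  if (length(object@lengthScales) < 1L ||
      !all(is.finite(object@lengthScales)) || any(object@lengthScales <= 0))
    msg <- c(msg, "lengthScales must be strictly positive and finite")
  if (length(object@signalVariance) != 1L ||
      !is.finite(object@signalVariance) || object@signalVariance <= 0)
    msg <- c(msg, "signalVariance must be a positive finite scalar")
  if (length(object@linearVariance) != 1L ||
      !is.finite(object@linearVariance) || object@linearVariance < 0)
    msg <- c(msg, "linearVariance must be a non-negative finite scalar")
  if (length(msg)) msg else TRUE
})

#' Fitted Gaussian process regression model
#'
#' Holds the kernel hyperparameters, learned noise variance, standardisation
#' constants and the cached Cholesky factorisation needed for exact posterior
#' prediction. Created by [fitGP()]; covariates are standardised and responses
#' centred internally, with constants stored so predictions are returned on
#' the original scale.
#'
#' @slot kernel A [GPKernel-class] with optimised hyperparameters (on the
#'   standardised covariate scale).
#' @slot noiseVariance Learned observation noise variance (response units
#'   squared); the normative noise term of the deviation Z-score.
#' @slot X Standardised training covariates (n x d).
#' @slot y Centred training responses.
#' @slot xCenter,xScale Per-covariate standardisation constants.
#' @slot yCenter Training response mean, restored at prediction.
#' @slot chol Upper-triangular Cholesky factor of the training covariance.
#' @slot alpha Precomputed solve of the covariance against the responses.
#' @slot jitter Diagonal jitter added for numerical stability.
#' @slot logLik Log marginal likelihood at the optimum.
#' @slot convergence Optimiser convergence code (0 = converged).
#' @export
setClass("GPModel",
  representation(
    kernel = "GPKernel",
    noiseVariance = "numeric",
    X = "matrix",
    y = "numeric",
    xCenter = "numeric",
    xScale = "numeric",
    yCenter = "numeric",
    chol = "matrix",
    alpha = "numeric",
    jitter = "numeric",
    logLik = "numeric",
    convergence = "integer"
  )
)

setValidity("GPModel", function(object) {
  msg <- character()
  if (object@noiseVariance <= 0) msg <- c(msg, "noiseVariance must be > 0")
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "training targets and inputs must have matching rows")
  if (!is.finite(object@logLik))
    msg <- c(msg, "logLik must be finite after a successful fit")
  if (length(msg)) msg else TRUE
})

#' Cohort container for normative modelling
#'
#' A [SummarizedExperiment-class] holding one cohort: the response matrix as
#' the `"response"` assay with locations as rows and subjects as columns, and
#' per-subject covariates, optional family identifiers (`familyId`) and
#' optional symptom scores (`symptom`) in `colData`. Constructed with
#' [NormativeCohort()], which accepts the subjects-by-locations orientation
#' used throughout the analysis functions.
#'
#' @seealso [NormativeCohort()], [estimateNormative()]
#' @export
setClass("NormativeCohort", contains = "SummarizedExperiment")

setValidity("NormativeCohort", function(object) {
  msg <- character()
  if (!"response" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'response' assay is required")
  cd <- SummarizedExperiment::colData(object)
  covs <- S4Vectors::metadata(object)$covariateNames
  if (is.null(covs) || length(covs) < 1L)
    msg <- c(msg, "at least one covariate is required (metadata covariateNames)")
  else if (!all(covs %in% colnames(cd)))
    msg <- c(msg, "all covariateNames must be columns of colData")
  else {
    cv <- as.matrix(as.data.frame(cd[, covs, drop = FALSE]))
    if (!all(is.finite(cv))) msg <- c(msg, "covariates must be finite (no missing values)")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "subject identifiers must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "location identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Fitted normative model set with cross-validated predictions
#'
#' A [SummarizedExperiment-class] produced by [estimateNormative()]. Assays
#' (locations x subjects): `z` (the normative probability map),
#' `cvMean`/`cvVar` (held-out predictive mean and noise-free function
#' variance), `cvNoise` (the normative noise variance of the model that made
#' each held-out prediction), and `response` (the observed data). `rowData`
#' carries per-location diagnostics (SMSE, log marginal likelihood, failure
#' flags, final-model noise variance); `metadata` carries the fold
#' assignment, the per-location all-data models and the configuration used.
#'
#' @seealso [npm()], [summarizeDeviance()], [centileSurface()]
#' @export
setClass("NormativeFit", contains = "SummarizedExperiment")

#' Maximum-likelihood extreme value distribution fit
#'
#' Gumbel or generalized extreme value (GEV) distribution fitted to a vector
#' of block-maxima deviance summaries, used to convert a subject's deviance
#' into an upper-tail probability.
#'
#' @slot family `"gumbel"` or `"gev"`.
#' @slot location,scale,shape Distribution parameters; `shape` is fixed at 0
#'   for the Gumbel family.
#' @slot nFit Number of observations used in the fit.
#' @slot logLik Maximised log-likelihood.
#' @seealso [fitEVD()], [evdPValue()]
#' @export
setClass("EVDFit",
  representation(
    family = "character",
    location = "numeric",
    scale = "numeric",
    shape = "numeric",
    nFit = "integer",
    logLik = "numeric"
  )
)

setValidity("EVDFit", function(object) {
  msg <- character()
  if (!object@family %in% c("gumbel", "gev"))
    msg <- c(msg, "family must be 'gumbel' or 'gev'")
  if (!is.finite(object@scale) || object@scale <= 0)
    msg <- c(msg, "scale must be a positive finite scalar")
  if (object@family == "gumbel" && object@shape != 0)
    msg <- c(msg, "gumbel fits must have shape 0")
  if (length(msg)) msg else TRUE
})
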