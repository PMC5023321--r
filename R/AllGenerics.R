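#' Learned normative noise variance
#'
#' The observation noise variance estimated from the normative cohort: the
#' third term of the deviation Z-score denominator. For a [GPModel-class]
#' this is a scalar; for a [NormativeFit-class] a per-location vector.
#'
#' @param object An object with a learned noise variance.
#' @rdname noiseVariance
#' @export
setGeneric("noiseVariance", function(object) standardGeneric("noiseVariance"))

#' Subject-by-location matrix accessors
#'
#' `responses()` returns the response matrix in subjects x locations
#' orientation; `covariates()` the subjects x covariates design matrix;
#' `familyIds()` the per-subject grouping labels (or NULL); `symptomScores()`
#' the per-subject symptom vector (or NULL).
#'
#' @param object A [NormativeCohort-class] or [NormativeFit-class].
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))

#' @rdname cohort-accessors
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @rdname cohort-accessors
#' @export
setGeneric("familyIds", function(object) standardGeneric("familyIds"))

#' @rdname cohort-accessors
#' @export
setGeneric("symptomScores", function(object) standardGeneric("symptomScores"))

#' Extract the normative probability map
#'
#' @param object A [NormativeFit-class].
#' @return Subjects x locations matrix of deviation Z-scores.
#' @export
setGeneric("npm", function(object) standardGeneric("npm"))

#' Fold assignment used for cross-validated estimation
#'
#' @param object A [NormativeFit-class].
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))
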