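#' Construct a cohort container
#'
#' Bundles a subjects x locations response matrix with per-subject covariates
#' and optional family labels and symptom scores into a
#' [NormativeCohort-class] (a `SummarizedExperiment` with locations as rows
#' and subjects as columns).
#'
#' @param responses Numeric matrix, subjects x locations. Row names (or
#'   `subjectIds`) identify subjects; column names (or `locationIds`)
#'   identify locations.
#' @param covariates Numeric matrix or data.frame, subjects x covariates,
#'   aligned with `responses` rows.
#' @param familyIds Optional vector of family/group labels per subject.
#' @param symptoms Optional numeric symptom score per subject.
#' @param subjectIds,locationIds Optional identifier vectors; defaults are
#'   taken from dimnames or generated (`S1..Sn`, `L1..Lp`).
#' @return A [NormativeCohort-class].
#' @examples
#' y <- matrix(rnorm(20), 4, 5)
#' x <- data.frame(auc = runif(4))
#' cohort <- NormativeCohort(y, x)
#' dim(responses(cohort))
#' @export
NormativeCohort <- function(responses, covariates, familyIds = NULL,
                            symptoms = NULL, subjectIds = NULL,
                            locationIds = NULL) {
  responses <- as.matrix(responses)
  if (is.null(subjectIds))
    subjectIds <- rownames(responses) %||% paste0("S", seq_len(nrow(responses)))
  if (is.null(locationIds))
    locationIds <- colnames(responses) %||% paste0("L", seq_len(ncol(responses)))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(responses))
    stop("covariates and responses disagree on subject count (",
         nrow(covariates), " vs ", nrow(responses), ")")
  if (is.null(colnames(covariates)) || any(!nzchar(colnames(covariates))))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  cd <- S4Vectors::DataFrame(covariates, row.names = subjectIds)
  if (!is.null(familyIds)) {
    if (length(familyIds) != nrow(responses))
      stop("familyIds length must equal subject count")
    cd$familyId <- as.character(familyIds)
  }
  if (!is.null(symptoms)) {
    if (length(symptoms) != nrow(responses))
      stop("symptoms length must equal subject count")
    cd$symptom <- as.numeric(symptoms)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(response = t(responses)),
    colData = cd)
  rownames(se) <- as.character(locationIds)
  colnames(se) <- as.character(subjectIds)
  S4Vectors::metadata(se)$covariateNames <- colnames(covariates)
  new("NormativeCohort", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname cohort-accessors
#' @export
setMethod("responses", "NormativeCohort", function(object)
  t(SummarizedExperiment::assay(object, "response")))

#' @rdname cohort-accessors
#' @export
setMethod("covariates", "NormativeCohort", function(object) {
  covs <- S4Vectors::metadata(object)$covariateNames
  m <- as.matrix(as.data.frame(
    SummarizedExperiment::colData(object)[, covs, drop = FALSE]))
  rownames(m) <- colnames(object)
  m
})

#' @rdname cohort-accessors
#' @export
setMethod("familyIds", "NormativeCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if ("familyId" %in% colnames(cd)) as.character(cd$familyId) else NULL
})

#' @rdname cohort-accessors
#' @export
setMethod("symptomScores", "NormativeCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if ("symptom" %in% colnames(cd)) as.numeric(cd$symptom) else NULL
})

setMethod("show", "NormativeCohort", function(object) {
  cat("NormativeCohort: ", ncol(object), " subjects x ", nrow(object),
      " locations\n", sep = "")
  cat("  covariates: ",
      paste(S4Vectors::metadata(object)$covariateNames, collapse = ", "),
      "\n", sep = "")
  cd <- SummarizedExperiment::colData(object)
  if ("familyId" %in% colnames(cd))
    cat("  families: ", length(unique(cd$familyId)), "\n", sep = "")
  if ("symptom" %in% colnames(cd))
    cat("  symptom scores: available\n")
})
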