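#' Run the full normative-modelling pipeline on a cohort
#'
#' Convenience orchestration of the four analysis stages: estimate the
#' normative models under grouped cross-validation, compute the normative
#' probability map, summarise per-subject deviance with trimmed block
#' maxima, make EVD-calibrated outlier calls with FDR-localised deviation
#' maps, and (when symptom scores are present) compute deviance-symptom
#' tail correlations per mode.
#'
#' @param cohort A [NormativeCohort-class].
#' @param k,seed,variant,restarts,maxit,finalModels Passed to
#'   [estimateNormative()].
#' @param tailFraction,trimTotal Passed to [summarizeDeviance()].
#' @param family,alpha,q Passed to [subjectInference()].
#' @param topFractions Passed to [tailCorrelation()].
#' @return A list with `fit`, `deviance`, `inference` and (when symptoms
#'   are available) `tailCorrelations` (a data.frame with a `mode` column).
#' @export
runNormativePipeline <- function(cohort, k = 10, seed = 1,
                                 variant = "se-ard", restarts = 2,
                                 maxit = 60, finalModels = FALSE,
                                 tailFraction = 0.01, trimTotal = 0.90,
                                 family = "gev", alpha = 0.05, q = 0.05,
                                 topFractions = c(0.01, 0.05, 0.1, 0.15, 0.2)) {
  fit <- estimateNormative(cohort, k = k, seed = seed, variant = variant,
                           restarts = restarts, maxit = maxit,
                           finalModels = finalModels)
  dev <- summarizeDeviance(fit, tailFraction = tailFraction,
                           trimTotal = trimTotal)
  inf <- subjectInference(dev, family = family, alpha = alpha, z = fit, q = q)
  out <- list(fit = fit, deviance = dev, inference = inf)
  sym <- symptomScores(cohort)
  if (!is.null(sym)) {
    feasible <- ceiling(topFractions * ncol(cohort)) >= 3
    if (!all(feasible)) {
      warning("dropping top fractions with fewer than 3 subjects: ",
              paste(topFractions[!feasible], collapse = ", "))
      topFractions <- topFractions[feasible]
    }
    tc <- do.call(rbind, lapply(colnames(dev)[colnames(dev) %in%
                                              .devianceModes], function(mode) {
      res <- tailCorrelation(dev[[mode]], sym, topFractions, mode = mode)
      cbind(mode = mode, res)
    }))
    out$tailCorrelations <- tc
  }
  out
}

#' Write pipeline outputs as TSV reports
#'
#' Writes `deviance.tsv` (per-subject deviances, EVD tail probabilities,
#' outlier calls and deviant-location counts), `fdr_mask.tsv` (per-subject
#' FDR-rejected locations), `tail_correlations.tsv` (r, p and n per top
#' fraction and mode) and `evd_fits.json`.
#'
#' @param result A list from [runNormativePipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writePipelineReport <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inf <- as.data.frame(result$inference)
  inf <- cbind(subject_id = rownames(inf), inf)
  write.table(inf, file.path(dir, "deviance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mask <- fdrMap(npm(result$fit),
                 q = S4Vectors::metadata(result$inference)$q)$mask
  .writeMatrixTsv(1 * mask, file.path(dir, "fdr_mask.tsv"))
  if (!is.null(result$tailCorrelations))
    write.table(result$tailCorrelations,
                file.path(dir, "tail_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  fits <- S4Vectors::metadata(result$inference)$evdFits
  evd <- lapply(fits, function(f) list(family = f@family,
                                       location = f@location,
                                       scale = f@scale, shape = f@shape,
                                       n = f@nFit, logLik = f@logLik))
  jsonlite::write_json(evd, file.path(dir, "evd_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
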