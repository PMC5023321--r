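# Subject-level abnormality indices: trimmed block-maxima summaries,
# extreme-value inference, FDR localization, tail correlations.

.devianceModes <- c("positive", "negative", "absolute")

# Trimmed mean of the extreme tail of one subject's Z values.
# m = ceiling(tailFraction * #valid); trim floor(trimTotal*m/2) from each
# end of the sorted tail block, always retaining >= 1 value.
.tailTrimmedMean <- function(v, tailFraction, trimTotal) {
  m <- max(1L, as.integer(ceiling(tailFraction * length(v))))
  tail_ <- sort(v, decreasing = TRUE)[seq_len(m)]
  perSide <- as.integer(floor(trimTotal * m / 2))
  if (m - 2L * perSide < 1L) perSide <- as.integer((m - 1L) %/% 2L)
  keep <- sort(tail_)[(perSide + 1L):(m - perSide)]
  mean(keep)
}

#' Summarize a subject's deviations into block-maxima scores
#'
#' Reduces each subject's set of location Z-scores to a robust extreme-tail
#' summary: the trimmed mean of the top `tailFraction` of the Z distribution
#' (positive deviance), of its negation (negative deviance, reported with a
#' negative sign), and of its absolute values (absolute deviance). The
#' default 1% tail with 90% total trim keeps the central survivors of the
#' sorted tail block (half the trim mass removed from each end, floor per
#' side, at least one survivor).
#'
#' @param object A [NormativeFit-class] or a subjects x locations Z matrix.
#' @param modes Which deviance modes to compute.
#' @param tailFraction Fraction of locations in the tail block (default
#'   0.01).
#' @param trimTotal Total fraction of the tail block removed before
#'   averaging (default 0.90).
#' @return A [S4Vectors::DataFrame] with one row per subject and one column
#'   per mode; `tailFraction` and `trimTotal` are recorded in its metadata.
#' @examples
#' z <- matrix(rnorm(3 * 200), 3, 200)
#' summarizeDeviance(z)
#' @export
summarizeDeviance <- function(object, modes = .devianceModes,
                              tailFraction = 0.01, trimTotal = 0.90) {
  z <- if (is(object, "NormativeFit")) npm(object) else as.matrix(object)
  modes <- match.arg(modes, .devianceModes, several.ok = TRUE)
  if (tailFraction <= 0 || tailFraction > 1) stop("tailFraction must be in (0, 1]")
  if (trimTotal < 0 || trimTotal >= 1) stop("trimTotal must be in [0, 1)")
  n <- nrow(z)
  out <- S4Vectors::DataFrame(row.names = rownames(z) %||% paste0("S", seq_len(n)))
  valid <- lapply(seq_len(n), function(i) z[i, is.finite(z[i, ])])
  nValid <- lengths(valid)
  if (any(nValid == 0))
    stop("no finite Z values for subject(s) ",
         paste(rownames(out)[nValid == 0], collapse = ", "))
  for (mode in modes) {
    out[[mode]] <- vapply(valid, function(v) {
      switch(mode,
        positive = .tailTrimmedMean(v, tailFraction, trimTotal),
        negative = -.tailTrimmedMean(-v, tailFraction, trimTotal),
        absolute = .tailTrimmedMean(abs(v), tailFraction, trimTotal))
    }, numeric(1))
  }
  S4Vectors::metadata(out) <- list(tailFraction = tailFraction,
                                   trimTotal = trimTotal)
  out
}

# --- extreme value distributions ------------------------------------------

.EULER_GAMMA <- 0.5772156649015329

.gumbelNLL <- function(par, x) {
  mu <- par[1]; sigma <- exp(par[2])
  zz <- (x - mu) / sigma
  length(x) * log(sigma) + sum(zz) + sum(exp(-zz))
}

.gevNLL <- function(par, x) {
  mu <- par[1]; sigma <- exp(par[2]); xi <- par[3]
  if (abs(xi) < 1e-8) return(.gumbelNLL(par[1:2], x))
  s <- 1 + xi * (x - mu) / sigma
  if (any(s <= 0)) return(1e10)
  length(x) * log(sigma) + (1 + 1 / xi) * sum(log(s)) + sum(s^(-1 / xi))
}

#' Fit an extreme value distribution by maximum likelihood
#'
#' Fits a Gumbel or generalized extreme value (GEV) distribution to a vector
#' of block-maxima summaries. Initial values come from the Gumbel moment
#' estimators (`scale = sqrt(6) * sd / pi`, `location = mean -
#' 0.5772 * scale`); the GEV fit additionally tries a fixed grid of shape
#' starting values, so the fit is a deterministic function of the data. With
#' fewer than 30 observations, or if the GEV optimisation fails, the Gumbel
#' family is used (with a warning in the failure case).
#'
#' @param x Numeric vector of deviance summaries (finite).
#' @param family `"gev"` (default) or `"gumbel"`.
#' @return An [EVDFit-class].
#' @examples
#' set.seed(1)
#' x <- -log(-log(runif(500)))  # standard Gumbel draws
#' fitEVD(x, family = "gumbel")
#' @export
fitEVD <- function(x, family = c("gev", "gumbel")) {
  family <- match.arg(family)
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("deviance values must be finite")
  if (length(x) < 2) stop("at least 2 observations required")
  if (family == "gev" && length(x) < 30) family <- "gumbel"

  sigma0 <- sqrt(6) * sd(x) / pi
  if (sigma0 <= 0) stop("deviance values are constant; cannot fit an EVD")
  mu0 <- mean(x) - .EULER_GAMMA * sigma0

  fitGumbel <- function() {
    opt <- optim(c(mu0, log(sigma0)), .gumbelNLL, x = x, method = "BFGS",
                 control = list(maxit = 500))
    new("EVDFit", family = "gumbel", location = opt$par[1],
        scale = exp(opt$par[2]), shape = 0, nFit = length(x),
        logLik = -opt$value)
  }

  if (family == "gumbel") return(fitGumbel())

  best <- NULL
  for (xi0 in c(-0.1, 1e-4, 0.1)) {
    opt <- tryCatch(
      optim(c(mu0, log(sigma0), xi0), .gevNLL, x = x, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    warning("GEV fit failed to converge; falling back to Gumbel")
    return(fitGumbel())
  }
  new("EVDFit", family = "gev", location = best$par[1],
      scale = exp(best$par[2]), shape = best$par[3], nFit = length(x),
      logLik = -best$value)
}

#' Upper-tail probability under a fitted extreme value distribution
#'
#' @param fit An [EVDFit-class].
#' @param q Numeric vector of deviance values.
#' @return Survival probabilities in (0, 1], monotone decreasing in `q`.
#' @export
evdPValue <- function(fit, q) {
  stopifnot(is(fit, "EVDFit"))
  mu <- fit@location; sigma <- fit@scale; xi <- fit@shape
  if (fit@family == "gumbel" || abs(xi) < 1e-8) {
    p <- 1 - exp(-exp(-(q - mu) / sigma))
  } else {
    s <- 1 + xi * (q - mu) / sigma
    p <- ifelse(s <= 0, if (xi > 0) 1 else 0, 1 - exp(-pmax(s, 0)^(-1 / xi)))
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Quantile function of a fitted extreme value distribution
#'
#' @param fit An [EVDFit-class].
#' @param p Probabilities in (0, 1).
#' @return Quantiles on the deviance scale.
#' @export
evdQuantile <- function(fit, p) {
  stopifnot(is(fit, "EVDFit"), all(p > 0 & p < 1))
  mu <- fit@location; sigma <- fit@scale; xi <- fit@shape
  if (fit@family == "gumbel" || abs(xi) < 1e-8)
    mu - sigma * log(-log(p))
  else
    mu + sigma * ((-log(p))^(-xi) - 1) / xi
}

setMethod("show", "EVDFit", function(object) {
  cat("EVDFit (", object@family, "): location ", signif(object@location, 4),
      ", scale ", signif(object@scale, 4),
      if (object@family == "gev") paste0(", shape ", signif(object@shape, 4)),
      " (n = ", object@nFit, ")\n", sep = "")
})

# --- FDR localization ------------------------------------------------------

#' Per-subject FDR-corrected deviation map
#'
#' Converts Z-scores to two-sided normal p-values and applies the
#' Benjamini-Hochberg step-up procedure, marking the locations where a
#' subject deviates from the norm at FDR level `q`. Non-finite entries
#' (e.g. failed locations) are excluded from the correction and reported as
#' `NA`.
#'
#' @param z Numeric vector of Z-scores for one subject, or a subjects x
#'   locations matrix (the procedure is applied independently per row).
#' @param q FDR level (default 0.05).
#' @return For a vector: a list with `mask` (logical), `p` and `pAdjusted`.
#'   For a matrix: a list of `mask` and `pAdjusted` matrices.
#' @examples
#' fdrMap(c(0.1, 4.2, -3.8, 1.0), q = 0.05)$mask
#' @export
fdrMap <- function(z, q = 0.05) {
  if (is.matrix(z)) {
    rows <- lapply(seq_len(nrow(z)), function(i) fdrMap(z[i, ], q))
    mask <- do.call(rbind, lapply(rows, `[[`, "mask"))
    padj <- do.call(rbind, lapply(rows, `[[`, "pAdjusted"))
    dimnames(mask) <- dimnames(padj) <- dimnames(z)
    return(list(mask = mask, pAdjusted = padj))
  }
  if (length(z) == 0) stop("empty Z input")
  ok <- is.finite(z)
  if (!any(ok)) stop("no finite Z values")
  p <- rep(NA_real_, length(z))
  padj <- rep(NA_real_, length(z))
  p[ok] <- 2 * pnorm(-abs(z[ok]))
  padj[ok] <- p.adjust(p[ok], method = "BH")
  mask <- padj <= q
  list(mask = mask, p = p, pAdjusted = padj)
}

#' Count deviating subjects per location
#'
#' Convenience overlap summary: for each location, how many subjects' FDR
#' masks flag it.
#'
#' @param mask Logical subjects x locations matrix from [fdrMap()].
#' @return Integer vector per location.
#' @export
deviantLocationCounts <- function(mask) {
  colSums(mask, na.rm = TRUE)
}

# --- tail correlations -----------------------------------------------------

#' Correlate deviance with symptoms in the most deviating subjects
#'
#' Ranks subjects by deviance magnitude and computes the Pearson correlation
#' between deviance and symptom scores within the top fraction of the
#' cohort, for each requested fraction. For the negative mode, subjects are
#' ranked by (and the correlation computed on) the magnitude of negative
#' deviance, so symptoms that grow with deviation yield positive
#' correlations.
#'
#' @param deviance Numeric vector of per-subject deviance scores (one mode).
#' @param symptoms Numeric symptom score per subject, aligned with
#'   `deviance`.
#' @param topFractions Fractions of the cohort to retain (default the 1, 5,
#'   10, 15 and 20% tails). Subset size is `ceiling(fraction * n)`.
#' @param mode Which deviance mode `deviance` holds; `"negative"` flips the
#'   sign to a magnitude before ranking and correlating.
#' @return A `data.frame` with columns `fraction`, `n`, `r`, `p`. A constant
#'   symptom vector within a subset gives `NA` for `r` and `p`.
#' @export
tailCorrelation <- function(deviance, symptoms,
                            topFractions = c(0.01, 0.05, 0.1, 0.15, 0.2),
                            mode = c("absolute", "positive", "negative")) {
  mode <- match.arg(mode)
  deviance <- as.numeric(deviance)
  symptoms <- as.numeric(symptoms)
  if (length(deviance) != length(symptoms))
    stop("deviance and symptoms must be aligned by subject")
  score <- if (mode == "negative") -deviance else deviance
  ord <- order(score, decreasing = TRUE)
  n <- length(score)
  res <- lapply(topFractions, function(f) {
    m <- as.integer(ceiling(f * n))
    if (m < 3)
      stop("top fraction ", f, " yields only ", m, " subjects (need >= 3)")
    idx <- ord[seq_len(m)]
    if (sd(symptoms[idx]) == 0 || sd(score[idx]) == 0)
      return(data.frame(fraction = f, n = m, r = NA_real_, p = NA_real_))
    ct <- cor.test(score[idx], symptoms[idx])
    data.frame(fraction = f, n = m, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' Subject-level outlier inference
#'
#' Fits an extreme value distribution per deviance mode across the cohort
#' and converts each subject's deviance into an upper-tail probability
#' (negative-mode deviances are first flipped to magnitudes, since the EVD
#' models block maxima). Optionally counts each subject's FDR-flagged
#' locations from the normative probability map.
#'
#' @param deviance A `DataFrame` from [summarizeDeviance()].
#' @param family EVD family passed to [fitEVD()].
#' @param alpha Outlier call threshold on the EVD tail probability.
#' @param z Optional subjects x locations Z matrix (or [NormativeFit-class])
#'   for per-subject FDR maps.
#' @param q FDR level for the deviant-location count.
#' @param primaryMode Mode used for the `evdP`/`isOutlier` columns
#'   (per-mode probabilities are always included as `evdP_<mode>`).
#' @return A `DataFrame` with per-subject deviances, per-mode EVD
#'   probabilities, the primary-mode outlier call and (if `z` is supplied)
#'   `nDeviantLocations`; the fitted [EVDFit-class] objects are attached as
#'   metadata.
#' @export
subjectInference <- function(deviance, family = c("gev", "gumbel"),
                             alpha = 0.05, z = NULL, q = 0.05,
                             primaryMode = "absolute") {
  family <- match.arg(family)
  modes <- intersect(.devianceModes, colnames(deviance))
  if (!primaryMode %in% modes)
    stop("primaryMode '", primaryMode, "' not among computed modes")
  out <- deviance
  fits <- list()
  for (mode in modes) {
    v <- if (mode == "negative") -deviance[[mode]] else deviance[[mode]]
    fits[[mode]] <- fitEVD(v, family = family)
    out[[paste0("evdP_", mode)]] <- evdPValue(fits[[mode]], v)
  }
  out$evdP <- out[[paste0("evdP_", primaryMode)]]
  out$isOutlier <- out$evdP < alpha
  if (!is.null(z)) {
    zm <- if (is(z, "NormativeFit")) npm(z) else as.matrix(z)
    out$nDeviantLocations <- as.integer(rowSums(fdrMap(zm, q)$mask,
                                                na.rm = TRUE))
  }
  S4Vectors::metadata(out) <- c(S4Vectors::metadata(deviance),
                                list(evdFits = fits, alpha = alpha, q = q,
                                     primaryMode = primaryMode))
  out
}
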