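# On-disk formats: TSV tables with a subject_id column, full-precision
# matrix TSVs, a versioned model bundle, optional NIfTI volumes via RNifti.

.BUNDLE_FORMAT <- "npmap-bundle-1"
.TRUTH_SCHEMA <- "npmap-truth-1"

# %.17g round-trips doubles exactly through text
.fmtNum <- function(x) sprintf("%.17g", x)

.writeMatrixTsv <- function(m, path, idColumn = "subject_id") {
  ch <- matrix(.fmtNum(m), nrow(m), ncol(m), dimnames = dimnames(m))
  df <- cbind(setNames(list(rownames(m)), idColumn),
              as.data.frame(ch, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readMatrixTsv <- function(path, idColumn = "subject_id") {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!idColumn %in% colnames(df))
    stop("column '", idColumn, "' missing from ", path)
  ids <- df[[idColumn]]
  m <- as.matrix(df[, setdiff(colnames(df), idColumn), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a per-subject table (covariates, symptoms or groups)
#'
#' Expects a header row and a subject identifier column.
#'
#' @param path TSV/CSV path (delimiter inferred from the extension).
#' @param idColumn Name of the subject identifier column.
#' @return A data.frame with subject IDs as row names.
#' @export
readSubjectTable <- function(path, idColumn = "subject_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE)
  if (!idColumn %in% colnames(df))
    stop("column '", idColumn, "' missing from ", path)
  rownames(df) <- as.character(df[[idColumn]])
  df[, setdiff(colnames(df), idColumn), drop = FALSE]
}

#' Write a synthetic cohort to a fixture directory
#'
#' Emits the file set the command-line interface consumes: `covariates.tsv`,
#' `responses.tsv`, `groups.tsv`, `symptoms.tsv` and `truth.json` (the
#' ground-truth record, versioned with a schema tag). Numeric values are
#' written with enough digits to round-trip exactly.
#'
#' @param sim A list from [simulateCohort()].
#' @param dir Output directory (created if missing).
#' @param nifti If TRUE, additionally write per-subject 3D NIfTI volumes and
#'   a mask under `dir/nifti/` (requires the RNifti package).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(sim, dir, nifti = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sim$cohort
  .writeMatrixTsv(responses(cohort), file.path(dir, "responses.tsv"))
  .writeMatrixTsv(covariates(cohort), file.path(dir, "covariates.tsv"))
  ids <- colnames(cohort)
  fams <- familyIds(cohort)
  if (!is.null(fams))
    write.table(data.frame(subject_id = ids, family_id = fams),
                file.path(dir, "groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  sym <- symptomScores(cohort)
  if (!is.null(sym))
    write.table(data.frame(subject_id = ids, symptom = .fmtNum(sym)),
                file.path(dir, "symptoms.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$schema <- .TRUTH_SCHEMA
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (nifti) .writeNiftiFixture(cohort, file.path(dir, "nifti"))
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [writeFixture()].
#' @return A list with `cohort` and (if present) `truth`.
#' @export
readFixture <- function(dir) {
  Y <- .readMatrixTsv(file.path(dir, "responses.tsv"))
  X <- .readMatrixTsv(file.path(dir, "covariates.tsv"))
  stopifnot(identical(rownames(Y), rownames(X)))
  fams <- sym <- NULL
  gp <- file.path(dir, "groups.tsv")
  if (file.exists(gp)) {
    g <- readSubjectTable(gp)
    fams <- as.character(g[rownames(Y), "family_id"])
  }
  sp <- file.path(dir, "symptoms.tsv")
  if (file.exists(sp)) {
    s <- readSubjectTable(sp)
    sym <- as.numeric(s[rownames(Y), "symptom"])
  }
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  list(cohort = NormativeCohort(Y, X, familyIds = fams, symptoms = sym),
       truth = truth)
}

# Arrange p locations in a near-cubic 3D grid; mask marks occupied voxels.
.niftiGeometry <- function(p) {
  side <- ceiling(p^(1 / 3))
  dims <- c(side, side, ceiling(p / side^2))
  mask <- array(FALSE, dims)
  mask[seq_len(p)] <- TRUE
  list(dims = dims, mask = mask)
}

.writeNiftiFixture <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI output")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Y <- responses(cohort)
  geo <- .niftiGeometry(ncol(Y))
  RNifti::writeNifti(RNifti::asNifti(geo$mask * 1L),
                     file.path(dir, "mask.nii.gz"))
  for (i in seq_len(nrow(Y))) {
    vol <- array(0, geo$dims)
    vol[geo$mask] <- Y[i, ]
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(dir, paste0(rownames(Y)[i], ".nii.gz")))
  }
  invisible(dir)
}

#' Flatten NIfTI volumes into a response matrix
#'
#' Reads one 3D volume per subject, applies a binary mask and returns the
#' subjects x locations matrix along with the location/voxel coordinate
#' table, so Z-maps can be written back into the same geometry.
#'
#' @param files NIfTI paths, one per subject (names become subject IDs).
#' @param maskFile Binary mask volume with the same dimensions.
#' @return List with `responses` (subjects x locations), `coordinates`
#'   (locations x 3 voxel indices) and `mask` (the mask array).
#' @export
readNiftiResponses <- function(files, maskFile) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI input")
  mask <- as.array(RNifti::readNifti(maskFile)) != 0
  coords <- which(mask, arr.ind = TRUE)
  ids <- names(files) %||% sub("\\.nii(\\.gz)?$", "", basename(files))
  Y <- t(vapply(files, function(f) {
    vol <- as.array(RNifti::readNifti(f))
    if (!all(dim(vol) == dim(mask)))
      stop("volume ", f, " does not match mask dimensions")
    vol[mask]
  }, numeric(sum(mask))))
  rownames(Y) <- ids
  colnames(Y) <- sprintf("L%05d", seq_len(ncol(Y)))
  list(responses = Y, coordinates = coords, mask = mask)
}

#' Write per-subject maps back into NIfTI geometry
#'
#' @param values Subjects x locations matrix (e.g. Z-scores or FDR masks).
#' @param mask Mask array from [readNiftiResponses()].
#' @param dir Output directory; one volume per subject, named by row.
#' @return `dir`, invisibly.
#' @export
writeNiftiMaps <- function(values, mask, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI output")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(values))) {
    vol <- array(0, dim(mask))
    vol[mask] <- values[i, ]
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(dir, paste0(rownames(values)[i], ".nii.gz")))
  }
  invisible(dir)
}

# --- model bundle ----------------------------------------------------------

#' Serialize a normative model set to a directory bundle
#'
#' Writes a versioned plain-text bundle: per-location hyperparameters and
#' normalisation constants, the training covariates and responses (needed
#' for exact GP re-prediction), the fold assignment, and a metadata record
#' with the configuration and a content hash.
#'
#' @param fit A [NormativeFit-class] with final models.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @seealso [loadModelBundle()]
#' @export
saveModelBundle <- function(fit, dir) {
  stopifnot(is(fit, "NormativeFit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  models <- S4Vectors::metadata(fit)$models
  if (all(vapply(models, is.null, logical(1))))
    stop("fit has no final models to serialize")
  X <- covariates(fit)
  Y <- responses(fit)
  .writeMatrixTsv(X, file.path(dir, "covariates.tsv"))
  .writeMatrixTsv(Y, file.path(dir, "responses.tsv"))
  d <- ncol(X)
  hp <- do.call(rbind, lapply(seq_along(models), function(j) {
    m <- models[[j]]
    if (is.null(m)) return(rep(NA_real_, 2 * d + d + 4))
    c(m@kernel@lengthScales, m@kernel@signalVariance,
      m@kernel@linearVariance, m@noiseVariance, m@yCenter,
      m@xCenter, m@xScale)
  }))
  colnames(hp) <- c(paste0("lengthScale_", colnames(X)), "signalVariance",
                    "linearVariance", "noiseVariance", "yCenter",
                    paste0("xCenter_", colnames(X)),
                    paste0("xScale_", colnames(X)))
  rownames(hp) <- rownames(fit)
  .writeMatrixTsv(hp, file.path(dir, "hyperparameters.tsv"),
                  idColumn = "location_id")
  write.table(data.frame(subject_id = colnames(fit), fold = foldAssignment(fit)),
              file.path(dir, "folds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- S4Vectors::metadata(fit)$config
  meta <- list(
    format = .BUNDLE_FORMAT,
    variant = cfg$variant,
    config = cfg,
    covariateNames = colnames(X),
    nSubjects = ncol(fit), nLocations = nrow(fit),
    configHash = .contentHash(cfg))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.contentHash <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(obj, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Load a serialized normative model bundle
#'
#' Reconstructs the per-location GP models from a [saveModelBundle()]
#' directory. Predictions from the reconstructed models are identical to
#' those of the original fit.
#'
#' @param dir Bundle directory.
#' @return A list with `models` (per-location [GPModel-class] or NULL),
#'   `covariates`, `responses`, `folds` and `meta`.
#' @export
loadModelBundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$format, .BUNDLE_FORMAT))
    stop("unrecognised bundle format: ", meta$format)
  X <- .readMatrixTsv(file.path(dir, "covariates.tsv"))
  Y <- .readMatrixTsv(file.path(dir, "responses.tsv"))
  hp <- .readMatrixTsv(file.path(dir, "hyperparameters.tsv"),
                       idColumn = "location_id")
  d <- ncol(X)
  models <- lapply(seq_len(nrow(hp)), function(j) {
    h <- hp[j, ]
    if (any(!is.finite(h[seq_len(d + 3)]))) return(NULL)
    kern <- ardKernel(h[seq_len(d)], h[d + 1],
                      variant = meta$variant,
                      linearVariance = h[d + 2])
    gpModel(kern, h[d + 3], X, Y[, j],
            xCenter = h[(d + 5):(2 * d + 4)],
            xScale = h[(2 * d + 5):(3 * d + 4)],
            yCenter = h[d + 4])
  })
  names(models) <- rownames(hp)
  folds <- readSubjectTable(file.path(dir, "folds.tsv"))
  list(models = models, covariates = X, responses = Y,
       folds = setNames(as.integer(folds$fold), rownames(folds)),
       meta = meta)
}

#' Predict normative responses from a loaded bundle
#'
#' @param bundle A list from [loadModelBundle()].
#' @param X New covariate rows (subjects x covariates).
#' @return As [predictCohort()]: matrices `mean`, `variance` and vector
#'   `noiseVariance`.
#' @export
predictBundle <- function(bundle, X) {
  X <- as.matrix(X)
  p <- length(bundle$models)
  mu <- matrix(NA_real_, nrow(X), p,
               dimnames = list(rownames(X), names(bundle$models)))
  va <- matrix(NA_real_, nrow(X), p, dimnames = dimnames(mu))
  nv <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    m <- bundle$models[[j]]
    if (is.null(m)) next
    pr <- predict(m, X)
    mu[, j] <- pr$mean
    va[, j] <- pr$variance
    nv[j] <- m@noiseVariance
  }
  list(mean = mu, variance = va, noiseVariance = nv)
}
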