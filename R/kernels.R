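#' Construct an ARD covariance kernel
#'
#' @param lengthScales Positive numeric vector, one length-scale per
#'   covariate. Larger values down-weight a covariate's relevance.
#' @param signalVariance Positive scalar marginal variance of the latent
#'   function.
#' @param variant `"se-ard"` (default) or `"linear-se-ard"` for a linear +
#'   squared-exponential sum.
#' @param linearVariance Variance of the linear component (ignored for
#'   `"se-ard"`).
#' @return A [GPKernel-class] object.
#' @examples
#' k <- ardKernel(c(1, 2), signalVariance = 1.5)
#' kernelMatrix(k, matrix(0, 1, 2), matrix(0, 1, 2))  # == 1.5 at zero distance
#' @export
ardKernel <- function(lengthScales, signalVariance = 1,
                      variant = c("se-ard", "linear-se-ard"),
                      linearVariance = 0) {
  variant <- match.arg(variant)
  new("GPKernel",
      variant = variant,
      lengthScales = as.numeric(lengthScales),
      signalVariance = as.numeric(signalVariance),
      linearVariance = as.numeric(linearVariance))
}

# Per-covariate squared-difference matrices between rows of A and B.
# Returned as a list of length d; shared across kernel evaluations so that
# hyperparameter optimisation only pays elementwise cost per step.
.sqdistList <- function(A, B) {
  lapply(seq_len(ncol(A)), function(k) outer(A[, k], B[, k], "-")^2)
}

.seMatrix <- function(D, lengthScales, signalVariance) {
  S <- 0
  for (k in seq_along(D)) S <- S + D[[k]] / lengthScales[k]^2
  signalVariance * exp(-0.5 * S)
}

#' Evaluate the kernel matrix between two sets of covariate rows
#'
#' @param kernel A [GPKernel-class].
#' @param A,B Numeric matrices whose rows are covariate vectors; both must
#'   have as many columns as `kernel` has length-scales.
#' @return The `nrow(A)` x `nrow(B)` matrix of pairwise covariances.
#' @export
kernelMatrix <- function(kernel, A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  d <- length(kernel@lengthScales)
  if (ncol(A) != d || ncol(B) != d)
    stop("covariate count (", ncol(A), ", ", ncol(B),
         ") does not match kernel length-scales (", d, ")")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("non-finite covariate values are not allowed")
  K <- .seMatrix(.sqdistList(A, B), kernel@lengthScales, kernel@signalVariance)
  if (kernel@variant == "linear-se-ard")
    K <- K + kernel@linearVariance * tcrossprod(A, B)
  K
}
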