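# Independent oracles: dense closed-form GP algebra, direct BH step-up
# enumeration, tail-trim arithmetic. Deliberately written without any use of
# the package's own linear-algebra/selection code paths.

# Scalar SE-ARD kernel evaluation (entrywise, no matrix shortcuts).
oracleKernelEntry <- function(a, b, lengthScales, signalVariance,
                              linearVariance = 0) {
  se <- signalVariance * exp(-0.5 * sum((a - b)^2 / lengthScales^2))
  se + linearVariance * sum(a * b)
}

oracleKernelMatrix <- function(A, B, lengthScales, signalVariance,
                               linearVariance = 0) {
  K <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      K[i, j] <- oracleKernelEntry(A[i, ], B[j, ], lengthScales,
                                   signalVariance, linearVariance)
  K
}

# Textbook GP posterior and log marginal likelihood via explicit inverse
# and determinant on the standardised training scale.
oracleGPPredict <- function(model, Xstar) {
  k <- model@kernel
  Xq <- sweep(sweep(as.matrix(Xstar), 2, model@xCenter, "-"),
              2, model@xScale, "/")
  lin <- if (k@variant == "linear-se-ard") k@linearVariance else 0
  K <- oracleKernelMatrix(model@X, model@X, k@lengthScales,
                          k@signalVariance, lin) +
    diag(model@noiseVariance + model@jitter, nrow(model@X))
  Ks <- oracleKernelMatrix(Xq, model@X, k@lengthScales, k@signalVariance, lin)
  Kss <- oracleKernelMatrix(Xq, Xq, k@lengthScales, k@signalVariance, lin)
  Kinv <- solve(K)
  mean <- as.numeric(Ks %*% Kinv %*% model@y) + model@yCenter
  cov <- Kss - Ks %*% Kinv %*% t(Ks)
  lml <- as.numeric(-0.5 * t(model@y) %*% Kinv %*% model@y -
                      0.5 * determinant(K)$modulus -
                      0.5 * length(model@y) * log(2 * pi))
  list(mean = mean, variance = pmax(diag(cov), 0), logLik = lml)
}

# Benjamini-Hochberg by direct step-up enumeration: find the largest i with
# p_(i) <= i*q/m and reject everything at or below it.
oracleBHReject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# Trimmed tail mean by literal enumeration of the stated rules.
oracleTailTrim <- function(v, tailFraction, trimTotal) {
  m <- ceiling(tailFraction * length(v))
  block <- sort(sort(v, decreasing = TRUE)[seq_len(m)])
  perSide <- floor(trimTotal * m / 2)
  if (m - 2 * perSide < 1) perSide <- (m - 1) %/% 2
  mean(block[(perSide + 1):(m - perSide)])
}

# Standard Gumbel sampler via inverse CDF.
rGumbel <- function(n, loc = 0, scale = 1) loc - scale * log(-log(runif(n)))

# Small deterministic cohort for engine tests.
makeTinyCohort <- function(n = 30, p = 4, seed = 1, signal = TRUE) {
  set.seed(seed)
  X <- cbind(a = runif(n), b = runif(n))
  Y <- sapply(seq_len(p), function(j)
    if (signal) sin(3 * X[, 1]) + rnorm(n, sd = 0.3) else rnorm(n))
  rownames(X) <- rownames(Y) <- sprintf("S%02d", seq_len(n))
  colnames(Y) <- sprintf("L%02d", seq_len(p))
  NormativeCohort(Y, X)
}
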