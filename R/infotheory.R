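# validate a discrete probability table (vector or matrix)
.checkProbTable <- function(p, tol = 1e-12) {
  if (!is.numeric(p) || !length(p)) stop("probability table must be numeric and nonempty")
  if (any(!is.finite(p))) stop("probability table contains non-finite values")
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > max(tol, 1e-12))
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}

#' Shannon entropy of a discrete distribution
#'
#' Plug-in entropy `-sum(p * log(p))` with the convention `0 * log(0) = 0`.
#' Serves as the exact discrete oracle against which the continuous kNN
#' estimators are validated.
#'
#' @param p probability vector (or matrix, flattened), nonnegative, summing
#'   to 1 within 1e-12
#' @return Entropy in nats.
#' @examples
#' entropyDiscrete(rep(0.25, 4))  # log(4)
#' @export
entropyDiscrete <- function(p) {
  .checkProbTable(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Plug-in discrete mutual information
#'
#' `H(X) + H(Y) - H(X, Y)` from a joint probability matrix; equals
#' `sum p(x,y) log(p(x,y) / (p(x) p(y)))`.
#'
#' @param joint joint probability matrix (rows = X, columns = Y)
#' @return MI in nats (>= 0 up to roundoff).
#' @examples
#' miPluginDiscrete(diag(2) / 2)  # log(2): one fair bit
#' @export
miPluginDiscrete <- function(joint) {
  if (!is.matrix(joint)) stop("joint must be a matrix")
  .checkProbTable(joint)
  entropyDiscrete(rowSums(joint)) + entropyDiscrete(colSums(joint)) -
    entropyDiscrete(joint)
}

# deterministic tie-breaking jitter: uniform noise of amplitude 1e-10 * SD
# under the fixed sub-seed, so kNN counts are well defined and results are
# reproducible; the caller's RNG state is untouched. Both series are jittered
# inside one seeded block (sequential draws).
.jitterTies <- function(...) {
  series <- list(...)
  .withSeed(.JITTER_SEED, {
    lapply(series, function(x) {
      s <- sd(x)
      if (s == 0) stop("degenerate constant series: zero variance")
      x + runif(length(x), -0.5, 0.5) * 1e-10 * s
    })
  })
}

.checkPair <- function(x, y, k) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("input contains NaN/Inf")
  if (length(x) <= k + 2) stop("need n > k + 2 samples")
}

#' KSG k-nearest-neighbor mutual information
#'
#' Kraskov-Stogbauer-Grassberger algorithm-1 estimate of the mutual
#' information between two continuous samples:
#' `psi(k) + psi(n) - mean(psi(nx + 1) + psi(ny + 1))`, with max-norm
#' neighborhoods of the k-th joint neighbor and strict marginal counts. A
#' deterministic micro-jitter (amplitude `1e-10 * SD`, fixed sub-seed) breaks
#' exact ties, so the estimate is fully reproducible. The estimate may be
#' slightly negative on independent data (finite-sample bias is not clipped).
#'
#' @param x,y numeric samples of equal length, `n > k + 2`, finite
#' @param k neighbor count (4 in the study)
#' @param theiler Theiler exclusion window in samples (0 for i.i.d. samples;
#'   set > 0 for serially correlated within-trial samples)
#' @param units `"nats"` or `"bits"`
#' @return A [CouplingEstimate-class].
#' @examples
#' xy <- genBivariateGaussian(2000, 0.6, seed = 1)
#' miKSG(xy[, 1], xy[, 2], k = 4)
#' @export
miKSG <- function(x, y, k = 4, theiler = 0, units = c("nats", "bits")) {
  units <- match.arg(units)
  .checkPair(x, y, k)
  j <- .jitterTies(x, y)
  v <- .ksg_mi_cpp(matrix(j[[1]]), matrix(j[[2]]), as.integer(k),
                   as.integer(theiler))
  if (units == "bits") v <- v / log(2)
  new("CouplingEstimate", value = v, estimator = "ksg1",
      params = list(k = as.integer(k), theiler = as.integer(theiler),
                    units = units),
      nSamples = length(x))
}
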