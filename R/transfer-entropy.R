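#' Delay-embed a series into state vectors
#'
#' Row t of the result is the reconstruction vector
#' `(s_t, s_{t - tau}, ..., s_{t - (d - 1) tau})`; the matrix has
#' `length(s) - (d - 1) * tau` rows, the first corresponding to time index
#' `(d - 1) * tau + 1`.
#'
#' @param series numeric series
#' @param d embedding dimension, >= 1
#' @param tau embedding delay in samples, >= 1
#' @return State matrix with `d` columns.
#' @examples
#' delayEmbed(1:6, d = 2, tau = 2)  # rows (3,1), (4,2), (5,3), (6,4)
#' @export
delayEmbed <- function(series, d, tau) {
  d <- as.integer(d); tau <- as.integer(tau)
  if (d < 1 || tau < 1) stop("d and tau must be >= 1")
  n <- length(series)
  if (n <= (d - 1) * tau) stop("series too short for this embedding")
  span <- (d - 1) * tau
  vapply(0:(d - 1), function(j) series[(span + 1 - j * tau):(n - j * tau)],
         numeric(n - span))
}

#' Data-driven Theiler window
#'
#' First zero crossing of the autocorrelation function, capped (default 100
#' samples), used to exclude serially correlated points from neighbor counts.
#'
#' @param x numeric series
#' @param cap maximum window, samples
#' @return Integer window length.
#' @export
theilerWindow <- function(x, cap = 100) {
  a <- acf(x, lag.max = min(cap, length(x) - 2), plot = FALSE,
           demean = TRUE)$acf[-1]
  w <- which(a <= 0)[1]
  if (is.na(w)) w <- cap
  as.integer(min(w, cap))
}

#' Select embedding parameters by the Ragwitz criterion
#'
#' Scores every (d, tau) pair on the grid by the mean-squared error of a
#' k-nearest-neighbor local-constant one-step predictor (the predicted
#' successor of a state is the mean successor of its k nearest embedded
#' neighbors, leave-one-out with Theiler exclusion), evaluated on a common
#' set of query times so all cells are comparable. Because the
#' cross-validated MSE is itself noisy, selection uses the one-standard-error
#' parsimony rule familiar from cross-validation: the smallest (d, then tau)
#' whose MSE lies within one standard error of the grid minimum is returned,
#' so statistically indistinguishable cells resolve toward the most
#' parsimonious embedding. Exact ties behave the same way.
#'
#' @param series numeric series; must not be constant
#' @param dRange candidate embedding dimensions
#' @param tauRange candidate embedding delays, samples
#' @param k neighbor count of the local predictor
#' @param theiler Theiler exclusion window, samples
#' @param nQueries number of query points the predictor is scored on
#'   (evenly spaced; capped by the number of valid states)
#' @return `list(d, tau, mse, se)`: the selected pair, the full MSE grid
#'   (rows = dRange, columns = tauRange) and the standard errors of its cells.
#' @export
ragwitzOptimize <- function(series, dRange = 1:6, tauRange = 1:10, k = 4,
                            theiler = 0, nQueries = 500) {
  if (!length(dRange) || !length(tauRange)) stop("empty search range")
  if (var(series) == 0) stop("degenerate constant series: cannot optimize embedding")
  dRange <- as.integer(sort(dRange)); tauRange <- as.integer(sort(tauRange))
  g <- .ragwitz_grid_cpp(as.numeric(series), dRange, tauRange,
                         as.integer(k), as.integer(theiler),
                         as.integer(nQueries))
  mse <- g$mse
  nq <- min(nQueries, length(series))
  se <- g$sdse / sqrt(nq)
  dimnames(mse) <- dimnames(se) <- list(d = dRange, tau = tauRange)
  imin <- which(mse == min(mse), arr.ind = TRUE)[1, ]
  thresh <- mse[imin[1], imin[2]] + se[imin[1], imin[2]]
  bd <- NULL
  for (di in seq_along(dRange)) {
    for (ti in seq_along(tauRange)) {
      if (mse[di, ti] <= thresh) {
        bd <- dRange[di]; bt <- tauRange[ti]
        break
      }
    }
    if (!is.null(bd)) break
  }
  list(d = bd, tau = bt, mse = mse, se = se)
}

# build aligned (future, source state, target state) matrices for TE
.teStates <- function(source, target, spec, sourceSpec) {
  n <- length(target)
  spanT <- (spec@d - 1L) * spec@tau
  spanS <- (sourceSpec@d - 1L) * sourceSpec@tau
  span <- max(spanT, spanS)
  u <- spec@u
  m <- n - u - span
  if (m <= spec@k + 2) stop("series too short for embedding plus prediction time")
  tIdx <- (span + 1):(n - u)           # state times
  Y <- delayEmbed(target, spec@d, spec@tau)
  X <- delayEmbed(source, sourceSpec@d, sourceSpec@tau)
  # row of an embedding matrix for time t is t - span_of_that_embedding
  Z <- Y[tIdx - spanT, , drop = FALSE]
  B <- X[tIdx - spanS, , drop = FALSE]
  A <- matrix(target[tIdx + u])
  list(A = A, B = B, Z = Z, m = m)
}

#' Transfer entropy by nearest-neighbor conditional mutual information
#'
#' Estimates the transfer entropy from `source` to `target` as the
#' conditional mutual information
#' `I(target_{t+u} ; source state_t | target state_t)` with uniform delay
#' embeddings, using the Frenzel-Pompe/KSG nearest-neighbor digamma estimator
#' (max-norm neighborhoods in the joint space, projected counts in the
#' marginal spaces, Theiler exclusion). Values are in nats and may be
#' slightly negative on uncoupled data (bias is not clipped).
#'
#' @param source,target numeric series of equal length
#' @param spec an [EmbeddingSpec-class] for the target state (d, tau), the
#'   prediction time u (samples), k and the Theiler window
#' @param sourceSpec optional [EmbeddingSpec-class] whose (d, tau) embed the
#'   source state (defaults to `spec`, i.e. a shared embedding)
#' @param units `"nats"` or `"bits"`
#' @return A [CouplingEstimate-class].
#' @examples
#' xy <- genCoupledAR(3000, cXY = 0.5, lag = 1, seed = 2)
#' teKSG(xy[, "x"], xy[, "y"], embeddingSpec(d = 1, tau = 1, u = 1, theiler = 10))
#' @export
teKSG <- function(source, target, spec, sourceSpec = spec,
                  units = c("nats", "bits")) {
  units <- match.arg(units)
  validObject(spec); validObject(sourceSpec)
  .checkPair(source, target, spec@k)
  j <- .jitterTies(source, target)
  st <- .teStates(j[[1]], j[[2]], spec, sourceSpec)
  v <- .fp_cmi_cpp(st$A, st$B, st$Z, spec@k, spec@theiler)
  if (units == "bits") v <- v / log(2)
  new("CouplingEstimate", value = v, estimator = "ksg_cmi",
      params = list(d = spec@d, tau = spec@tau, u = spec@u, k = spec@k,
                    theiler = spec@theiler, dSource = sourceSpec@d,
                    tauSource = sourceSpec@tau, units = units),
      nSamples = st$m)
}

#' Scan the prediction time and return the maximizing u
#'
#' Evaluates [teKSG()] on a grid of prediction times (milliseconds, default
#' the 10-49 ms physiological conduction-delay range) and returns the u that
#' maximizes the transfer entropy, ties broken toward the smallest u.
#'
#' @param source,target numeric series of equal length
#' @param spec an [EmbeddingSpec-class]; its `u` slot is overridden by the grid
#' @param fs sampling rate, Hz, used to convert ms to samples
#' @param uGridMs prediction times in ms (nonempty)
#' @param sourceSpec optional source embedding, as in [teKSG()]
#' @return `list(bestU, profile)`: `bestU` in ms, `profile` a data.frame with
#'   columns `u_ms`, `u_samples`, `te_nats`.
#' @export
scanPredictionTime <- function(source, target, spec, fs,
                               uGridMs = seq(10, 49, by = 1),
                               sourceSpec = spec) {
  if (!length(uGridMs)) stop("empty prediction-time grid")
  uSamp <- msToSamples(uGridMs, fs)
  te <- vapply(uSamp, function(us) {
    sp <- spec; sp@u <- us
    couplingValue(teKSG(source, target, sp, sourceSpec = sourceSpec))
  }, numeric(1))
  best <- which.max(te)  # first maximum = smallest u on ties
  list(bestU = uGridMs[best],
       profile = data.frame(u_ms = uGridMs, u_samples = uSamp, te_nats = te))
}

#' Bidirectional transfer entropy between LFP and EMG
#'
#' Computes the descending (LFP to EMG) and ascending (EMG to LFP) transfer
#' entropies with independently Ragwitz-optimized embeddings per signal and a
#' shared prediction-time policy: either a fixed u or a scan over a ms grid
#' (the maximizing u is used, per direction).
#'
#' @param lfpSeries,emgSeries numeric series of equal length
#' @param fs sampling rate, Hz
#' @param k neighbor count
#' @param dRange,tauRange Ragwitz search grids
#' @param uMs fixed prediction time in ms (used when `scanU = FALSE`)
#' @param scanU scan u over `uGridMs` instead of using `uMs`
#' @param uGridMs scan grid in ms
#' @param theiler `"auto"` (per-target [theilerWindow()]) or an integer
#' @param nQueries Ragwitz predictor query budget
#' @return `list(desc, asc)` of [CouplingEstimate-class] objects; each has
#'   the embeddings used (and `bestU` under a scan) in its `params`.
#' @export
teBidirectional <- function(lfpSeries, emgSeries, fs, k = 4, dRange = 1:6,
                            tauRange = 1:10, uMs = 25, scanU = FALSE,
                            uGridMs = seq(10, 49, by = 1), theiler = "auto",
                            nQueries = 300) {
  if (!length(lfpSeries) || !length(emgSeries)) stop("zero-length input")
  th <- function(x) if (identical(theiler, "auto")) theilerWindow(x) else as.integer(theiler)
  embL <- ragwitzOptimize(lfpSeries, dRange, tauRange, k = k, theiler = th(lfpSeries),
                          nQueries = nQueries)
  embE <- ragwitzOptimize(emgSeries, dRange, tauRange, k = k, theiler = th(emgSeries),
                          nQueries = nQueries)
  one <- function(src, tgt, embS, embT) {
    spec <- embeddingSpec(d = embT$d, tau = embT$tau, u = msToSamples(uMs, fs),
                          k = k, theiler = th(tgt))
    sspec <- embeddingSpec(d = embS$d, tau = embS$tau, u = spec@u, k = k,
                           theiler = spec@theiler)
    if (scanU) {
      sc <- scanPredictionTime(src, tgt, spec, fs, uGridMs, sourceSpec = sspec)
      spec@u <- msToSamples(sc$bestU, fs)
      est <- teKSG(src, tgt, spec, sourceSpec = sspec)
      est@params$bestU <- sc$bestU
      est@params$profile <- sc$profile
      est
    } else {
      teKSG(src, tgt, spec, sourceSpec = sspec)
    }
  }
  list(desc = one(lfpSeries, emgSeries, embL, embE),
       asc  = one(emgSeries, lfpSeries, embE, embL))
}
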