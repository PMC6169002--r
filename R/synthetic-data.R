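#' Bivariate Gaussian samples with known mutual information
#'
#' Draws i.i.d. samples from a standard bivariate Gaussian with correlation
#' `rho`; the exact mutual information is [analyticGaussianMI()].
#'
#' @param n sample count, >= 2
#' @param rho correlation, strictly inside (-1, 1)
#' @param seed integer seed (the caller's RNG state is left untouched)
#' @return An `n x 2` matrix with columns `x`, `y`.
#' @examples
#' xy <- genBivariateGaussian(1000, 0.6, seed = 1)
#' cor(xy[, "x"], xy[, "y"])
#' @export
genBivariateGaussian <- function(n, rho, seed = 1L) {
  if (abs(rho) >= 1) stop("rho must satisfy |rho| < 1")
  if (n < 2) stop("n must be >= 2")
  .withSeed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    cbind(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
  })
}

#' Exact mutual information of a bivariate Gaussian
#'
#' @param rho correlation, strictly inside (-1, 1)
#' @return MI in nats: `-0.5 * log(1 - rho^2)`.
#' @export
analyticGaussianMI <- function(rho) {
  if (any(abs(rho) >= 1)) stop("rho must satisfy |rho| < 1")
  -0.5 * log(1 - rho^2)
}

#' Simulate a bidirectionally coupled pair of AR(1) processes
#'
#' Generates `x[t] = aX x[t-1] + cYX y[t-lag] + eX[t]` and
#' `y[t] = aY y[t-1] + cXY x[t-lag] + eY[t]` with independent Gaussian
#' innovations; a burn-in is discarded. The linear-Gaussian transfer entropy
#' of this system is available exactly from [analyticLinearTE()].
#'
#' @param n output length (after burn-in)
#' @param aX,aY AR coefficients, strictly inside (-1, 1)
#' @param cXY coupling x -> y; `cYX` coupling y -> x
#' @param cYX coupling y -> x
#' @param lag coupling lag in samples, >= 1
#' @param noiseSd innovation standard deviation (both processes)
#' @param seed integer seed
#' @param burn burn-in samples discarded
#' @return An `n x 2` matrix with columns `x`, `y`.
#' @export
genCoupledAR <- function(n, aX = 0.5, aY = 0.5, cXY = 0, cYX = 0, lag = 1,
                         noiseSd = 1, seed = 1L, burn = 500L) {
  if (abs(aX) >= 1 || abs(aY) >= 1)
    stop("nonstationary AR coefficients: require |aX| < 1 and |aY| < 1")
  if (lag < 1) stop("lag must be >= 1")
  if (n <= 10 * lag) stop("n must be much larger than lag")
  total <- n + burn
  out <- .withSeed(seed, {
    ex <- rnorm(total, sd = noiseSd)
    ey <- rnorm(total, sd = noiseSd)
    .sim_coupled_ar_cpp(ex, ey, aX, aY, cXY, cYX, as.integer(lag),
                        as.integer(burn))
  })
  colnames(out) <- c("x", "y")
  out
}

#' Exact transfer entropy of the linear-Gaussian coupled AR system
#'
#' For the system of [genCoupledAR()], all variables are jointly Gaussian, so
#' the transfer entropy with one-lag (d = 1, tau = 1) states equals the
#' Granger log-variance ratio
#' `0.5 * log(Var(target_{t+u} | target state) / Var(target_{t+u} | both states))`.
#' Conditional variances are computed exactly from the stationary covariance
#' of the companion VAR (discrete Lyapunov equation solved by doubling), not
#' by simulation.
#'
#' @param aX,aY AR coefficients, strictly inside (-1, 1)
#' @param cXY,cYX coupling coefficients (x -> y and y -> x)
#' @param lag coupling lag in samples
#' @param sdX,sdY innovation standard deviations
#' @param direction `"xy"` for TE(x -> y), `"yx"` for TE(y -> x)
#' @param d embedding dimension of both conditioning states (delay 1)
#' @param u prediction time in samples
#' @return Transfer entropy in nats (always >= 0).
#' @examples
#' analyticLinearTE(cXY = 0, cYX = 0)  # 0: no coupling
#' @export
analyticLinearTE <- function(aX = 0.5, aY = 0.5, cXY = 0, cYX = 0, lag = 1,
                             sdX = 1, sdY = 1, direction = c("xy", "yx"),
                             d = 1, u = 1) {
  direction <- match.arg(direction)
  if (abs(aX) >= 1 || abs(aY) >= 1) stop("nonstationary model")
  p <- max(lag, 1)
  # companion VAR(1) over S_t = (x_t, y_t, x_{t-1}, y_{t-1}, ...), dim 2p
  A <- matrix(0, 2 * p, 2 * p)
  A[1, 1] <- aX
  A[2, 2] <- aY
  A[1, 2 * (lag - 1) + 2] <- cYX   # y_{t-lag} -> x_t
  A[2, 2 * (lag - 1) + 1] <- cXY   # x_{t-lag} -> y_t
  if (p > 1) for (i in seq_len(2 * (p - 1))) A[i + 2, i] <- 1
  Q <- matrix(0, 2 * p, 2 * p)
  Q[1, 1] <- sdX^2
  Q[2, 2] <- sdY^2
  # doubling iteration for Sigma = A Sigma A' + Q
  S <- Q; Ak <- A
  for (i in 1:60) {
    S <- S + Ak %*% S %*% t(Ak)
    Ak <- Ak %*% Ak
    if (max(abs(Ak)) < 1e-300) break
  }
  # indices of x_t and y_t coordinates at lags 0..p-1 within S_t
  idx <- function(var, lagk) 2 * lagk + if (var == "x") 1 else 2
  src <- if (direction == "xy") "x" else "y"
  tgt <- if (direction == "xy") "y" else "x"
  if (d > p) stop("embedding dimension d exceeds companion order; increase lag or reduce d")
  # joint covariance of (S_{t+u}, S_t): Cov(S_{t+u}, S_t) = A^u Sigma
  Au <- diag(2 * p)
  for (i in seq_len(u)) Au <- Au %*% A
  C <- rbind(cbind(S, Au %*% S), cbind(S %*% t(Au), S))
  m <- 2 * p
  iFut <- idx(tgt, 0)                       # target_{t+u}, block 1
  iTgt <- m + vapply(0:(d - 1), function(l) idx(tgt, l), 1)  # target state, block 2
  iSrc <- m + vapply(0:(d - 1), function(l) idx(src, l), 1)  # source state, block 2
  condVar <- function(given) {
    Sgg <- C[given, given, drop = FALSE]
    cfg <- C[iFut, given, drop = FALSE]
    C[iFut, iFut] - cfg %*% solve(Sgg, t(cfg))
  }
  v1 <- condVar(iTgt)
  v2 <- condVar(c(iTgt, iSrc))
  max(0, 0.5 * as.numeric(log(v1 / v2)))
}

# spectrally shaped 1/f noise (white noise filtered to 1/sqrt(f) amplitude),
# unit SD, zero DC
.pinkNoise <- function(n) {
  W <- fft(rnorm(n))
  k <- 0:(n - 1)
  fr <- pmin(k, n - k)
  scale <- ifelse(fr == 0, 0, 1 / sqrt(fr))
  x <- Re(fft(W * scale, inverse = TRUE)) / n
  x / sd(x)
}

# band-limited unit-SD noise by FFT masking of white noise: numerically exact
# for arbitrarily narrow bands (IIR designs are ill-conditioned at very low
# normalized edge frequencies)
.bandNoise <- function(n, fs, lo, hi) {
  W <- fft(rnorm(n))
  fr <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  W[fr < lo | fr > hi] <- 0
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sd(x)
}

# delay x by k samples, padding the head with the first value
.delaySamples <- function(x, k) {
  if (k == 0) return(x)
  n <- length(x)
  c(rep(x[1], k), x[seq_len(n - k)])
}

#' Generate a synthetic stimulus-locked LFP/EMG recording
#'
#' Emulates a paired cortico-muscular recording under a pulsed ultrasound
#' protocol.
#'
#' The LFP is a band-limited (0.5-200 Hz) broadband cortical process plus a
#' narrowband low-beta rhythm (13-19 Hz), 1/f-like noise, slow drift and
#' 50 Hz line contamination. The EMG is a rate-modulated broadband carrier
#' (10-200 Hz): the motor activation is driven, after the corticomuscular
#' conduction delay, by the beta rhythm and by the rectified broadband core
#' (weight `fineWeight`), scaled by `couplingDesc`; intrinsic muscle noise of
#' SD `noiseSd` is added, and that intrinsic component feeds back into the
#' LFP with the weaker gain `couplingAsc` at the same delay, giving genuine
#' bidirectional, asymmetric coupling. The delayed beta rhythm carries the
#' zero-lag dependence that mutual information measures (corticomuscular
#' beta coherence); the broadband component pins the transfer-entropy
#' prediction-time peak at the conduction delay.
#'
#' In the post-stimulation phase the coupling gains are multiplied by
#' `1 + ntbGainSlope * NTB`, and the same factor scales the beta-rhythm
#' amplitude (stimulation raises cortical excitability, mirroring the
#' increased post-stimulation LFP amplitude seen in vivo; this also induces
#' the amplitude-coupling correlations the report tabulates). With a zero
#' slope the pre and post records are bit-identical under the same seed, so
#' the phase label changes nothing but the gains.
#'
#' @param protocol a [StimProtocol-class]
#' @param cfg a [SynthConfig-class]
#' @param phase `"pre"` or `"post"` stimulation
#' @param duration record length in seconds; default `nTrials * iti + 2`,
#'   which accommodates all trial windows. An explicit shorter duration that
#'   cannot hold `nTrials` triggers is an error.
#' @param oscAmp amplitude of the beta rhythm in the LFP (and, delayed, in
#'   the motor drive) relative to the unit-SD broadband core. Set to 0 for a
#'   purely broadband descending coupling (useful when validating conduction-
#'   delay recovery: narrowband coherence biases prediction-time estimates,
#'   a known property of oscillatory sources).
#' @param fineWeight weight of the rectified broadband component in the
#'   motor drive, relative to the beta component
#' @param actDepth modulation depth of the motor activation per unit of
#'   (normalized) drive and unit coupling gain
#' @return A [TimeSeriesRecording-class] with triggers every ITI seconds.
#' @examples
#' rec <- genCMCRecording(stimProtocol(ntb = 100),
#'                        synthConfig(nTrials = 3, seed = 7), "pre")
#' rec
#' @export
genCMCRecording <- function(protocol, cfg, phase = c("pre", "post"),
                            duration = NULL, oscAmp = 0.8, fineWeight = 1.0,
                            actDepth = 0.3) {
  phase <- match.arg(phase)
  validObject(protocol); validObject(cfg)
  fs <- cfg@fs
  iti <- protocol@iti
  son <- sonicationDuration(protocol)
  need <- cfg@nTrials * iti + 2
  if (is.null(duration)) duration <- need
  if (duration < need)
    stop(sprintf("record too short: %d trials at iti = %g s need %.1f s, got %.1f s",
                 cfg@nTrials, iti, need, duration))
  n <- round(duration * fs)
  triggers <- 1 + (seq_len(cfg@nTrials) - 1) * iti

  gd <- cfg@couplingDesc
  ga <- cfg@couplingAsc
  excit <- 1
  if (phase == "post") {
    mult <- 1 + cfg@ntbGainSlope * protocol@ntb
    gd <- gd * mult
    ga <- ga * mult
    excit <- mult
  }
  delaySamp <- round(cfg@conductionDelay / 1000 * fs)
  tt <- (seq_len(n) - 1) / fs

  comps <- .withSeed(cfg@seed, {
    list(z    = .bandNoise(n, fs, 0.5, 200),  # broadband cortical core
         oscU = .bandNoise(n, fs, 13, 19),    # low-beta rhythm, unit SD
         pink = .pinkNoise(n),
         car  = .bandNoise(n, fs, 10, 200),   # muscle carrier
         fbn  = .bandNoise(n, fs, 10, 200),   # intrinsic muscle noise
         driftPhase = runif(1, 0, 2 * pi),
         linePhase  = runif(1, 0, 2 * pi))
  })

  osc <- excit * oscAmp * comps$oscU
  lfpCore <- comps$z + osc + 0.3 * comps$pink
  rms <- sd(lfpCore)
  drift <- cfg@driftAmp * rms * sin(2 * pi * 0.2 * tt + comps$driftPhase)
  line <- cfg@lineNoiseAmp * rms * sin(2 * pi * 50 * tt + comps$linePhase)

  # motor drive: delayed beta rhythm + delayed rectified broadband core
  fine <- abs(.delaySamples(comps$z, delaySamp))
  drive <- .delaySamples(osc, delaySamp) + fineWeight * (fine - mean(fine))
  drive <- drive / sd(drive)
  activation <- pmax(1 + gd * actDepth * drive, 0.05)

  emgSig <- activation * comps$car + cfg@noiseSd * comps$fbn + line + drift
  lfpSig <- lfpCore + ga * .delaySamples(comps$fbn, delaySamp) + line + drift

  new("TimeSeriesRecording", lfp = lfpSig, emg = emgSig, fs = fs,
      triggerTimes = triggers,
      metadata = list(phase = phase, ntb = protocol@ntb, iti = iti,
                      sonicationDuration = son, seed = cfg@seed,
                      couplingDescEffective = gd, couplingAscEffective = ga,
                      conductionDelayMs = cfg@conductionDelay))
}
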