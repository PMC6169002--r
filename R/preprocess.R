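#' Zero-phase IIR notch filter
#'
#' Removes a narrow line component (default 50 Hz mains) with a second-order
#' IIR notch (biquad) applied forward-backward, so the net filter has zero
#' phase and squared magnitude.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz; must exceed `2 * notchFreq`
#' @param notchFreq notch center frequency, Hz
#' @param bandwidth -3 dB bandwidth, Hz (default 1.4 Hz, i.e. Q ~ 35 at 50 Hz)
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 2000; t <- seq(0, 2, by = 1/fs)
#' y <- notchFilter(sin(2 * pi * 50 * t), fs)   # mains tone suppressed
#' @export
notchFilter <- function(x, fs, notchFreq = 50, bandwidth = 1.4) {
  if (notchFreq >= fs / 2) stop("notchFreq must be below the Nyquist frequency fs/2")
  if (!length(x)) stop("empty input series")
  # RBJ audio-EQ cookbook notch biquad
  w0 <- 2 * pi * notchFreq / fs
  q <- notchFreq / bandwidth
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::filtfilt(b / a[1], a / a[1], x)
}

#' Remove slow baseline drift
#'
#' Subtracts a centered moving-average baseline (edge-reflected padding), a
#' transparent zero-phase high-pass that removes drift below roughly
#' `1/baselineWindow` Hz without ringing.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param baselineWindow moving-average window, seconds; at least `2/fs` and
#'   no longer than the record
#' @return Detrended signal, same length as `x`.
#' @export
removeBaseline <- function(x, fs, baselineWindow = 0.5) {
  if (!length(x)) stop("empty input series")
  if (baselineWindow < 2 / fs) stop("baselineWindow must be >= 2/fs")
  w <- round(baselineWindow * fs)
  if (w %% 2 == 0) w <- w + 1
  n <- length(x)
  if (w > n) stop("baseline window longer than the record")
  half <- (w - 1) / 2
  xp <- if (half > 0) c(x[half:1], x, x[n:(n - half + 1)]) else x
  cs <- cumsum(c(0, xp))
  baseline <- (cs[(w + 1):(n + w)] - cs[1:n]) / w
  x - baseline
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param lo,hi band edges, Hz; require `0 < lo < hi < fs/2`
#' @param order filter order (of the prototype low-pass)
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 2000; t <- seq(0, 2, by = 1/fs)
#' y <- bandpassFilter(sin(2 * pi * 100 * t), fs, 10, 200)  # passes ~unchanged
#' @export
bandpassFilter <- function(x, fs, lo, hi, order = 4) {
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("invalid band: require 0 < lo < hi < fs/2")
  if (!length(x)) stop("empty input series")
  bt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bt, x)
}

#' Full-wave rectification
#'
#' Elementwise absolute value, the standard EMG rectification; idempotent.
#'
#' @param x numeric signal
#' @return `abs(x)`.
#' @export
rectifyEMG <- function(x) abs(x)

#' Apply the full preprocessing chain to a recording
#'
#' Per channel: notch (50 Hz) -> baseline removal -> band-pass (0.5-200 Hz for
#' LFP, 10-200 Hz for EMG); the EMG is then full-wave rectified (set
#' `rectify = FALSE` to defer rectification, e.g. to after trial cutting).
#' All stages are zero-phase and preserve sample count.
#'
#' @param recording a [TimeSeriesRecording-class]
#' @param spec a [FilterSpec-class]
#' @param rectify rectify the EMG at the end of the chain (default TRUE,
#'   following rectification-before-cutting order)
#' @return A preprocessed [TimeSeriesRecording-class].
#' @export
preprocessRecording <- function(recording, spec = filterSpec(), rectify = TRUE) {
  fs <- recording@fs
  chain <- function(x, band) {
    x <- notchFilter(x, fs, spec@notchFreq, spec@notchBandwidth)
    x <- removeBaseline(x, fs, spec@baselineWindow)
    bandpassFilter(x, fs, band[1], band[2])
  }
  l <- chain(recording@lfp, spec@lfpBand)
  e <- chain(recording@emg, spec@emgBand)
  if (rectify) e <- rectifyEMG(e)
  new("TimeSeriesRecording", lfp = l, emg = e, fs = fs,
      triggerTimes = recording@triggerTimes,
      metadata = c(recording@metadata,
                   list(preprocessed = TRUE, rectified = rectify)))
}

#' Cut a recording into pre-/post-stimulation trials
#'
#' For each trigger at time t, the pre-stimulation trial covers
#' `[t - windowPre, t)` and the post-stimulation trial
#' `[t + sonication, t + sonication + windowPost)`, where the sonication
#' duration NTB/PRF comes from the protocol. Triggers whose windows fall
#' outside the record are dropped (count reported via `message()` and stored
#' in the trial sets).
#'
#' @param recording a [TimeSeriesRecording-class]
#' @param windowPre,windowPost window lengths, seconds
#' @param protocol a [StimProtocol-class]
#' @return `list(pre = TrialSet, post = TrialSet)`.
#' @export
segmentTrials <- function(recording, windowPre = 1, windowPost = 1, protocol) {
  fs <- recording@fs
  son <- sonicationDuration(protocol)
  if (windowPre + son + windowPost > protocol@iti)
    stop("windows overlap adjacent trials: windowPre + sonication + windowPost > iti")
  n <- length(recording@lfp)
  lpre <- round(windowPre * fs)
  lpost <- round(windowPost * fs)
  if (lpre < 1 || lpost < 1) stop("windows must span at least one sample")
  preL <- list(); postL <- list()
  preE <- list(); postE <- list()
  dropped <- 0L
  for (t in recording@triggerTimes) {
    i0 <- round((t - windowPre) * fs) + 1      # first pre sample
    i1 <- i0 + lpre - 1                        # last pre sample (< trigger)
    j0 <- round((t + son) * fs) + 1            # first post sample
    j1 <- j0 + lpost - 1
    if (i0 < 1 || j1 > n) { dropped <- dropped + 1L; next }
    preL[[length(preL) + 1]] <- recording@lfp[i0:i1]
    preE[[length(preE) + 1]] <- recording@emg[i0:i1]
    postL[[length(postL) + 1]] <- recording@lfp[j0:j1]
    postE[[length(postE) + 1]] <- recording@emg[j0:j1]
  }
  if (dropped > 0)
    message(dropped, " trigger(s) dropped: window exceeded record bounds")
  if (!length(preL)) stop("no usable triggers after windowing")
  ntb <- if (!is.null(recording@metadata$ntb)) recording@metadata$ntb else protocol@ntb
  mk <- function(ll, ee, phase, window) {
    new("TrialSet", lfp = do.call(cbind, ll), emg = do.call(cbind, ee),
        fs = fs, phase = phase, ntb = ntb, window = window,
        nDropped = dropped)
  }
  list(pre  = mk(preL, preE, "pre", c(-windowPre, 0)),
       post = mk(postL, postE, "post", c(son, son + windowPost)))
}
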