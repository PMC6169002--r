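#' Ultrasound stimulation protocol
#'
#' Pulsing parameters of a pulsed transcranial ultrasound stimulation (pTUS)
#' train: acoustic intensity (AI), number of acoustic cycles per pulse (NC),
#' pulse repetition frequency (PRF), number of tone bursts (NTB) and
#' inter-trial interval (ITI). The sonication duration is derived as NTB/PRF,
#' so at PRF = 1 kHz an NTB of 100..300 bursts corresponds to 0.1..0.3 s.
#'
#' @slot acousticIntensity acoustic intensity in W/cm^2 (informational only;
#'   no acoustic physics is modeled)
#' @slot nCyclesPerPulse number of acoustic cycles per tone burst
#' @slot prf pulse repetition frequency in Hz
#' @slot ntb number of tone bursts per train
#' @slot iti inter-trial interval in seconds
#' @slot fundamentalFreq transducer fundamental frequency in Hz
#' @seealso [stimProtocol()], [sonicationDuration()]
#' @export
setClass("StimProtocol",
  slots = c(
    acousticIntensity = "numeric",
    nCyclesPerPulse   = "numeric",
    prf               = "numeric",
    ntb               = "numeric",
    iti               = "numeric",
    fundamentalFreq   = "numeric"
  )
)

setValidity("StimProtocol", function(object) {
  msg <- character()
  if (object@ntb < 1) msg <- c(msg, "ntb must be >= 1")
  if (object@prf <= 0) msg <- c(msg, "prf must be > 0")
  if (object@iti <= object@ntb / object@prf)
    msg <- c(msg, "iti must exceed the sonication duration ntb/prf")
  if (length(msg)) msg else TRUE
})

#' Construct a stimulation protocol
#'
#' Defaults follow the study conditions: AI = 1.10 W/cm^2, NC = 250,
#' PRF = 1 kHz, ITI = 3.6 s, 500 kHz transducer.
#'
#' @param ntb number of tone bursts (one of 100, 150, 200, 250, 300 in the
#'   study design, but any count >= 1 is accepted)
#' @param prf pulse repetition frequency, Hz
#' @param iti inter-trial interval, seconds; must exceed `ntb/prf`
#' @param acousticIntensity acoustic intensity, W/cm^2 (metadata only)
#' @param nCyclesPerPulse acoustic cycles per tone burst (metadata only)
#' @param fundamentalFreq transducer frequency, Hz (metadata only)
#' @return A [StimProtocol-class] object.
#' @examples
#' p <- stimProtocol(ntb = 250)
#' sonicationDuration(p)  # 0.25 s
#' @export
stimProtocol <- function(ntb = 250, prf = 1000, iti = 3.6,
                         acousticIntensity = 1.10, nCyclesPerPulse = 250,
                         fundamentalFreq = 5e5) {
  new("StimProtocol",
      acousticIntensity = acousticIntensity,
      nCyclesPerPulse = nCyclesPerPulse,
      prf = prf, ntb = ntb, iti = iti,
      fundamentalFreq = fundamentalFreq)
}

#' Synthetic recording configuration
#'
#' Parameters of the synthetic cortico-muscular recording generator: sampling
#' rate, trial count, bidirectional coupling gains, conduction delay, the
#' NTB-dependent post-stimulation gain slope, nuisance amplitudes and the seed.
#'
#' @slot fs sampling rate, Hz
#' @slot nTrials number of stimulation trials in the record
#' @slot couplingDesc descending (cortex to muscle) coupling gain, unitless
#' @slot couplingAsc ascending (muscle to cortex) coupling gain, unitless
#' @slot conductionDelay corticomuscular conduction delay, ms; must lie in
#'   [10, 49] so the prediction-time scan can recover it
#' @slot ntbGainSlope post-stimulation multiplicative gain increase per tone
#'   burst: post gains = pre gains * (1 + ntbGainSlope * NTB)
#' @slot lineNoiseAmp 50 Hz line contamination amplitude, fraction of LFP RMS
#' @slot driftAmp slow baseline drift amplitude, fraction of LFP RMS
#' @slot noiseSd standard deviation of the intrinsic EMG noise, unitless
#' @slot seed integer seed governing all random draws
#' @seealso [synthConfig()], [genCMCRecording()]
#' @export
setClass("SynthConfig",
  slots = c(
    fs              = "numeric",
    nTrials         = "numeric",
    couplingDesc    = "numeric",
    couplingAsc     = "numeric",
    conductionDelay = "numeric",
    ntbGainSlope    = "numeric",
    lineNoiseAmp    = "numeric",
    driftAmp        = "numeric",
    noiseSd         = "numeric",
    seed            = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (object@nTrials < 1) msg <- c(msg, "nTrials must be >= 1")
  if (object@couplingDesc < 0 || object@couplingAsc < 0)
    msg <- c(msg, "coupling gains must be >= 0")
  if (object@conductionDelay < 10 || object@conductionDelay > 49)
    msg <- c(msg, "conductionDelay must lie in [10, 49] ms")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic recording configuration
#'
#' Defaults encode the study conditions plus generator choices documented in
#' the methods vignette: 2 kHz sampling, 30 trials, descending gain 1.0 with a
#' weaker ascending feedback 0.3, 25 ms conduction delay (center of the 10-49
#' ms scan range), gain slope 0.006 per tone burst, line/drift nuisances at
#' 10% of signal RMS, and intrinsic EMG noise SD 0.5.
#'
#' @param fs sampling rate, Hz
#' @param nTrials stimulation trials per record
#' @param couplingDesc,couplingAsc descending/ascending coupling gains
#' @param conductionDelay conduction delay, ms, in [10, 49]
#' @param ntbGainSlope post-stimulation gain increase per tone burst
#' @param lineNoiseAmp,driftAmp nuisance amplitudes, fractions of LFP RMS
#' @param noiseSd intrinsic EMG noise standard deviation
#' @param seed integer seed
#' @return A [SynthConfig-class] object.
#' @export
synthConfig <- function(fs = 2000, nTrials = 30, couplingDesc = 1.0,
                        couplingAsc = 0.3, conductionDelay = 25,
                        ntbGainSlope = 0.006, lineNoiseAmp = 0.1,
                        driftAmp = 0.1, noiseSd = 0.5, seed = 1L) {
  new("SynthConfig", fs = fs, nTrials = nTrials, couplingDesc = couplingDesc,
      couplingAsc = couplingAsc, conductionDelay = conductionDelay,
      ntbGainSlope = ntbGainSlope, lineNoiseAmp = lineNoiseAmp,
      driftAmp = driftAmp, noiseSd = noiseSd, seed = as.integer(seed))
}

#' Paired LFP/EMG recording
#'
#' A synchronously sampled pair of single-channel signals (local field
#' potential and electromyogram) with stimulation trigger times.
#'
#' @slot lfp LFP samples, arbitrary units
#' @slot emg EMG samples, arbitrary units; same length as `lfp`
#' @slot fs sampling rate, Hz
#' @slot triggerTimes stimulation onset times in seconds, strictly increasing,
#'   all within the record
#' @slot metadata free-form list (phase, ntb, generator settings, ...)
#' @seealso [genCMCRecording()], [readRecording()], [segmentTrials()]
#' @export
setClass("TimeSeriesRecording",
  slots = c(
    lfp          = "numeric",
    emg          = "numeric",
    fs           = "numeric",
    triggerTimes = "numeric",
    metadata     = "list"
  )
)

setValidity("TimeSeriesRecording", function(object) {
  msg <- character()
  if (length(object@lfp) != length(object@emg))
    msg <- c(msg, "lfp and emg must have equal length")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  tt <- object@triggerTimes
  if (length(tt)) {
    if (any(diff(tt) <= 0)) msg <- c(msg, "triggerTimes must be strictly increasing")
    dur <- (length(object@lfp) - 1) / object@fs
    if (any(tt < 0) || any(tt > dur))
      msg <- c(msg, "all triggerTimes must lie inside the record")
    iti <- object@metadata$iti
    if (!is.null(iti) && length(tt) > 1 && any(diff(tt) < iti - 1e-9))
      msg <- c(msg, "triggerTimes must be spaced >= iti")
  }
  if (length(msg)) msg else TRUE
})

#' Filter specification for preprocessing
#'
#' @slot notchFreq line frequency to remove, Hz
#' @slot notchBandwidth -3 dB bandwidth of the notch, Hz
#' @slot lfpBand LFP band-pass edges (low, high), Hz
#' @slot emgBand EMG band-pass edges (low, high), Hz
#' @slot baselineWindow moving-average window for baseline removal, seconds
#' @seealso [filterSpec()], [preprocessRecording()]
#' @export
setClass("FilterSpec",
  slots = c(
    notchFreq      = "numeric",
    notchBandwidth = "numeric",
    lfpBand        = "numeric",
    emgBand        = "numeric",
    baselineWindow = "numeric"
  )
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  for (nm in c("lfpBand", "emgBand")) {
    b <- slot(object, nm)
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      msg <- c(msg, sprintf("%s must satisfy 0 < low < high", nm))
  }
  if (object@notchFreq <= 0) msg <- c(msg, "notchFreq must be > 0")
  if (object@baselineWindow <= 0) msg <- c(msg, "baselineWindow must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a filter specification
#'
#' Defaults follow the study's preprocessing: 50 Hz notch, LFP band-passed to
#' 0.5-200 Hz, EMG to 10-200 Hz, with a 0.5 s moving-average baseline window.
#'
#' @param notchFreq,notchBandwidth notch center frequency and bandwidth, Hz
#' @param lfpBand,emgBand band edges, Hz
#' @param baselineWindow baseline moving-average window, seconds
#' @return A [FilterSpec-class] object.
#' @export
filterSpec <- function(notchFreq = 50, notchBandwidth = 1.4,
                       lfpBand = c(0.5, 200), emgBand = c(10, 200),
                       baselineWindow = 0.5) {
  new("FilterSpec", notchFreq = notchFreq, notchBandwidth = notchBandwidth,
      lfpBand = lfpBand, emgBand = emgBand, baselineWindow = baselineWindow)
}

#' Per-condition trial windows
#'
#' Equal-length paired LFP/EMG windows cut around stimulation triggers, stored
#' as samples-by-trials matrices.
#'
#' @slot lfp LFP trial matrix, samples x trials
#' @slot emg EMG trial matrix, samples x trials
#' @slot fs sampling rate, Hz
#' @slot phase `"pre"` or `"post"` relative to stimulation
#' @slot ntb number of tone bursts of the condition
#' @slot window window offsets (start, end) in seconds relative to the trigger
#'   (post windows are offset by the sonication duration)
#' @slot nDropped triggers dropped because their window exceeded record bounds
#' @seealso [segmentTrials()]
#' @export
setClass("TrialSet",
  slots = c(
    lfp      = "matrix",
    emg      = "matrix",
    fs       = "numeric",
    phase    = "character",
    ntb      = "numeric",
    window   = "numeric",
    nDropped = "integer"
  )
)

setValidity("TrialSet", function(object) {
  msg <- character()
  if (!identical(dim(object@lfp), dim(object@emg)))
    msg <- c(msg, "lfp and emg trial matrices must have identical dimensions")
  if (!object@phase %in% c("pre", "post"))
    msg <- c(msg, "phase must be 'pre' or 'post'")
  if (length(msg)) msg else TRUE
})

#' State-space embedding specification
#'
#' Parameters governing delay-embedding and nearest-neighbor estimation:
#' embedding dimension d, embedding delay tau (samples), prediction time u
#' (samples), neighbor count k and the Theiler exclusion window (samples).
#'
#' @slot d embedding dimension, >= 1
#' @slot tau embedding delay in samples, >= 1
#' @slot u prediction time in samples, >= 1 (use [msToSamples()] to convert
#'   from milliseconds)
#' @slot k nearest-neighbor count (4 in the study)
#' @slot theiler Theiler exclusion window in samples, >= 0
#' @seealso [embeddingSpec()], [teKSG()], [ragwitzOptimize()]
#' @export
setClass("EmbeddingSpec",
  slots = c(d = "integer", tau = "integer", u = "integer",
            k = "integer", theiler = "integer")
)

setValidity("EmbeddingSpec", function(object) {
  msg <- character()
  if (object@d < 1) msg <- c(msg, "d must be >= 1")
  if (object@tau < 1) msg <- c(msg, "tau must be >= 1")
  if (object@u < 1) msg <- c(msg, "u must be >= 1 sample")
  if (object@k < 1) msg <- c(msg, "k must be >= 1")
  if (object@theiler < 0) msg <- c(msg, "theiler must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an embedding specification
#'
#' @param d embedding dimension
#' @param tau embedding delay, samples
#' @param u prediction time, samples (default 50 samples = 25 ms at 2 kHz)
#' @param k neighbor count
#' @param theiler Theiler window, samples
#' @return An [EmbeddingSpec-class] object.
#' @export
embeddingSpec <- function(d = 2, tau = 1, u = 50, k = 4, theiler = 0) {
  new("EmbeddingSpec", d = as.integer(d), tau = as.integer(tau),
      u = as.integer(u), k = as.integer(k), theiler = as.integer(theiler))
}

#' Convert a prediction time in milliseconds to samples
#'
#' @param ms time in milliseconds
#' @param fs sampling rate, Hz
#' @return Integer sample count (rounded); errors if it rounds to 0.
#' @export
msToSamples <- function(ms, fs) {
  s <- as.integer(round(ms / 1000 * fs))
  if (any(s < 1)) stop("prediction time converts to 0 samples at fs = ", fs)
  s
}

#' A mutual-information or transfer-entropy estimate
#'
#' Holds the estimate (in nats), estimator metadata, the sample count it was
#' computed from, and, when a surrogate test was run, the surrogate
#' distribution and its p-value.
#'
#' @slot value estimate in nats (may be slightly negative: kNN estimators are
#'   not clipped, preserving estimator statistics across trials)
#' @slot estimator estimator name (`"ksg1"`, `"ksg_cmi"`)
#' @slot params estimator parameters (k, theiler, embedding, direction, ...)
#' @slot nSamples number of state vectors used
#' @slot surrogates surrogate estimates in nats (empty when no test was run)
#' @slot pValue surrogate p-value, or NA
#' @seealso [miKSG()], [teKSG()], [surrogateTest()]
#' @export
setClass("CouplingEstimate",
  slots = c(
    value      = "numeric",
    estimator  = "character",
    params     = "list",
    nSamples   = "integer",
    surrogates = "numeric",
    pValue     = "numeric"
  ),
  prototype = list(surrogates = numeric(0), pValue = NA_real_)
)

setValidity("CouplingEstimate", function(object) {
  msg <- character()
  if (length(object@value) != 1) msg <- c(msg, "value must be a scalar")
  k <- object@params$k
  if (!is.null(k) && object@nSamples < k + 2)
    msg <- c(msg, "nSamples must be >= k + 2 for kNN estimates")
  if (length(msg)) msg else TRUE
})

#' Full-study analysis report
#'
#' Output of [runFullStudy()]: the per-trial estimates table, per-condition
#' summaries (mean +/- SD across subjects), repeated-measures ANOVA tables,
#' the amplitude-coupling correlation table, and provenance (config, seed).
#'
#' @slot estimates per-trial estimates (subject, ntb, phase, measure,
#'   direction, trial, value_nats, p_surrogate, lfp_amp, emg_amp)
#' @slot miSummary mutual-information summary per ntb x phase
#' @slot teSummary transfer-entropy summary per ntb x phase x direction
#' @slot anovaTables list of rANOVA result tables
#' @slot correlations amplitude-vs-coupling Pearson correlations per ntb
#' @slot config the run configuration used
#' @slot seed master seed of the run
#' @seealso [runFullStudy()], [buildReport()]
#' @export
setClass("AnalysisReport",
  slots = c(
    estimates    = "data.frame",
    miSummary    = "data.frame",
    teSummary    = "data.frame",
    anovaTables  = "list",
    correlations = "data.frame",
    config       = "list",
    seed         = "integer"
  )
)
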